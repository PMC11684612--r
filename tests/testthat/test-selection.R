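test_that("representative selection returns optimal medoids on small cases", {
  # 3 samples, k = 1: sample 2 minimises total distance (0.1 + 0.8 = 0.9)
  # Construct compositions realising approximately these dissimilarities.
  v <- rbind(S1 = c(0.50, 0.50, 0.00),
             S2 = c(0.45, 0.45, 0.10),
             S3 = c(0.02, 0.03, 0.95))
  colnames(v) <- paste0("f", 1:3)
  ft <- feature_table(v, mode = "relative")
  d <- as.matrix(dissimilarity_matrix(ft))
  oracle <- pam_exhaustive(d, 1)
  sel <- select_representative(ft, 1)
  expect_equal(sel$selected, rownames(d)[oracle$medoids])

  withr::with_seed(17, {
    for (rep in 1:25) {
      n <- sample(4:8, 1)
      k <- sample(2:3, 1)
      tbl <- random_count_table(n, 10, relative = TRUE)
      dm <- as.matrix(dissimilarity_matrix(tbl))
      sel <- select_representative(tbl, k)
      obj <- sum(apply(dm[, sel$selected, drop = FALSE], 1, min))
      expect_equal(obj, pam_exhaustive(dm, k)$objective, tolerance = 1e-12)
    }
  })
})

test_that("representative selection saturates at k = n and is locally optimal", {
  withr::with_seed(23, {
    ft <- random_count_table(7, 9, relative = TRUE)
    expect_setequal(select_representative(ft, 7)$selected, sample_ids(ft))

    # no single medoid <-> non-medoid swap lowers the objective
    sel <- select_representative(ft, 3)
    dm <- as.matrix(dissimilarity_matrix(ft))
    obj <- function(meds) sum(apply(dm[, meds, drop = FALSE], 1, min))
    base <- obj(sel$selected)
    for (out in sel$selected)
      for (swap_in in setdiff(sample_ids(ft), sel$selected)) {
        cand <- c(setdiff(sel$selected, out), swap_in)
        expect_gte(obj(cand), base - 1e-12)
      }
  })
})

test_that("diverse selection ranks by inverse Simpson, descending", {
  # lambdas 0.9, 0.5, 0.34: the most even sample wins at k = 1
  v <- rbind(A = c(0.9439, 0.0561, 0.0000),   # lambda ~ 0.894
             B = c(0.5000, 0.5000, 0.0000),   # lambda = 0.5
             C = c(0.4000, 0.3000, 0.3000))   # lambda = 0.34
  v <- v / rowSums(v)
  colnames(v) <- paste0("f", 1:3)
  ft <- feature_table(v, mode = "relative")
  expect_equal(select_diverse(ft, 1)$selected, "C")
  full <- select_diverse(ft, 3)
  expect_equal(full$selected, c("C", "B", "A"))
  expect_true(all(diff(full$scores) <= 0))
})

test_that("ranking selections are nested across k", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      sim <- simulate_cohort(synthetic_config(
        n_samples = 25, n_asv_features = 40, n_otu_groups = 15,
        depth_mean = 3000, seed = sample.int(1e6, 1)))
      rel <- to_relative_frequency(sim$asv)
      for (f in list(function(k) select_diverse(rel, k),
                     function(k) select_discriminant(rel, sim$phenotype, k),
                     function(k) select_distinct(rel, sim$phenotype, k))) {
        s5 <- f(5)$selected; s10 <- f(10)$selected; s20 <- f(20)$selected
        expect_true(all(s5 %in% s10))
        expect_true(all(s10 %in% s20))
        expect_equal(s5, s10[1:5])
      }
    }
  })
})

test_that("extreme selection picks the most dissimilar pair first", {
  # pair (A, B) maximally dissimilar (BC ~ 1), the rest mutually close
  v <- rbind(A = c(0.98, 0.01, 0.01, 0.00),
             B = c(0.00, 0.01, 0.01, 0.98),
             C = c(0.30, 0.35, 0.30, 0.05),
             D = c(0.32, 0.33, 0.30, 0.05))
  v <- v / rowSums(v)
  colnames(v) <- paste0("f", 1:4)
  ft <- feature_table(v, mode = "relative")
  expect_setequal(select_extreme(ft, 2)$selected, c("A", "B"))
  expect_setequal(select_extreme(ft, 4)$selected, c("A", "B", "C", "D"))
  expect_error(select_extreme(ft, 1), "k must be")
})

test_that("extreme selection follows the merge order of the inverted metric", {
  withr::with_seed(37, {
    for (rep in 1:15) {
      n <- sample(4:6, 1)
      linkage <- sample(c("average", "complete", "single"), 1)
      ft <- random_count_table(n, 8, relative = TRUE)
      inv <- 1 - as.matrix(dissimilarity_matrix(ft))
      diag(inv) <- 0
      oracle <- merge_order_oracle(inv, linkage)
      for (k in 2:n)
        expect_equal(select_extreme(ft, k, linkage = linkage)$selected,
                     oracle[1:k],
                     info = sprintf("n=%d k=%d linkage=%s", n, k, linkage))
    }
  })
})

test_that("extreme selection is invariant under sample relabeling", {
  withr::with_seed(41, {
    ft <- random_count_table(6, 8, relative = TRUE)
    sel1 <- select_extreme(ft, 3)
    perm <- sample(6)
    ft2 <- feature_table(ft$values[perm, ], mode = "relative")
    sel2 <- select_extreme(ft2, 3)
    expect_setequal(sel1$selected, sel2$selected)
  })
})

test_that("class centroids are arithmetic means of member rows", {
  v <- rbind(S1 = c(0.2, 0.8), S2 = c(0.6, 0.4))
  colnames(v) <- c("f1", "f2")
  ft <- feature_table(v, mode = "relative")
  expect_equal(unname(class_centroid(ft, c("S1", "S2"))), c(0.4, 0.6))
  expect_equal(unname(class_centroid(ft, "S1")), c(0.2, 0.8))
  expect_equal(sum(class_centroid(ft, c("S1", "S2"))), 1)
  expect_error(class_centroid(ft, character(0)), "empty")
})

test_that("discriminant and distinct orders match the centroid-distance oracle", {
  fx <- discriminant_fixture()
  dist <- discriminant_fixture_distances()
  asc <- names(sort(dist))
  disc <- select_discriminant(fx$table, fx$phenotype, 4)
  expect_equal(disc$selected, asc)
  expect_equal(unname(disc$scores), unname(dist[asc]), tolerance = 1e-12)

  dis <- select_distinct(fx$table, fx$phenotype, 4)
  expect_equal(dis$selected, rev(asc))
  # saturation: same set, reversed order
  expect_setequal(disc$selected, dis$selected)
  # strict ranks: the extremes disagree at k = 1
  expect_false(select_discriminant(fx$table, fx$phenotype, 1)$selected ==
                 select_distinct(fx$table, fx$phenotype, 1)$selected)
})

test_that("a sample equal to the opposite centroid is selected first", {
  cen <- c(0.35, 0.45, 0.20)
  v <- rbind(S1 = cen,                       # case sample AT control centroid
             S2 = c(0.80, 0.10, 0.10),
             S3 = c(0.30, 0.50, 0.20),
             S4 = c(0.40, 0.40, 0.20))
  colnames(v) <- paste0("f", 1:3)
  ft <- feature_table(v, mode = "relative")
  ph <- impute_phenotype(c(S1 = "case", S2 = "case",
                           S3 = "control", S4 = "control"))
  sel <- select_discriminant(ft, ph, 1)
  expect_equal(sel$selected, "S1")
  expect_equal(unname(sel$scores), 0, tolerance = 1e-12)
})

test_that("phenotype-aware selection rejects an empty class", {
  fx <- discriminant_fixture()
  ph <- impute_phenotype(c(S1 = "control", S2 = "control",
                           S3 = "control", S4 = "control"))
  expect_error(select_discriminant(fx$table, ph, 2), "no members")
})

test_that("selection requires relative mode and a valid k", {
  withr::with_seed(2, {
    counts <- random_count_table(5, 6)
    expect_error(select_diverse(counts, 2), "relative")
    rel <- to_relative_frequency(counts)
    expect_error(select_diverse(rel, 0), "k must be")
    expect_error(select_diverse(rel, 6), "k must be")
  })
})

test_that("selection methods are deterministic", {
  withr::with_seed(55, {
    sim <- simulate_cohort(synthetic_config(
      n_samples = 20, n_asv_features = 30, n_otu_groups = 12,
      depth_mean = 2000, seed = 99))
    rel <- to_relative_frequency(sim$asv)
    for (m in selection_methods()) {
      s1 <- select_subsample(rel, m, 6, phenotype = sim$phenotype)
      s2 <- select_subsample(rel, m, 6, phenotype = sim$phenotype)
      expect_identical(s1$selected, s2$selected)
    }
  })
})
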