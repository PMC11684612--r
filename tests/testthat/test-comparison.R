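test_that("pairwise overlap handles identity, disjoint and partial cases", {
  expect_equal(pairwise_overlap(c("A", "B"), c("A", "B"))$overlap_fraction, 1)
  expect_equal(pairwise_overlap(c("A", "B"), c("X", "Y"))$overlap_fraction, 0)
  rep <- pairwise_overlap(c("A", "B", "C", "D"), c("A", "B", "X", "Y"))
  expect_equal(rep$overlap_fraction, 0.5)
  expect_equal(unname(rep$intersections),
               c(2L, 2L, 2L))  # both, only_a, only_b
  expect_false(rep$size_mismatch)
})

test_that("pairwise overlap is symmetric and flags size mismatches", {
  withr::with_seed(83, {
    a <- sample(LETTERS, 8); b <- sample(LETTERS, 8)
    r1 <- pairwise_overlap(a, b); r2 <- pairwise_overlap(b, a)
    expect_equal(r1$overlap_fraction, r2$overlap_fraction)
    expect_equal(unname(r1$intersections["both"]),
                 unname(r2$intersections["both"]))
  })
  mm <- pairwise_overlap(c("A", "B", "C"), c("A", "B"))
  expect_true(mm$size_mismatch)
  expect_equal(mm$overlap_fraction, 2 / 3)
})

test_that("upset counts equal brute-force membership enumeration", {
  sels <- list(one = c("A", "B", "C"), two = c("B", "C", "D"),
               three = c("C", "D", "E"))
  rep <- upset_counts(sels)
  # brute force over every sample in the union
  union <- sort(unique(unlist(sels)))
  want <- table(vapply(union, function(s)
    paste(names(sels)[vapply(sels, function(set) s %in% set, TRUE)],
          collapse = "&"), ""))
  got <- stats::setNames(rep$intersections$count, rep$intersections$pattern)
  expect_equal(got[names(want)], stats::setNames(as.integer(want), names(want)))
  # exclusive intersections partition the union
  expect_equal(sum(rep$intersections$count), length(union))
})

test_that("upset counts cover identity and disjoint special cases", {
  same <- upset_counts(list(a = c("X", "Y"), b = c("X", "Y")))
  expect_equal(same$intersections$pattern, "a&b")
  expect_equal(same$intersections$count, 2L)
  disj <- upset_counts(list(a = "P", b = "Q", c = "R"))
  expect_setequal(disj$intersections$pattern, c("a", "b", "c"))
  expect_true(all(disj$intersections$count == 1L))
  expect_error(upset_counts(list(a = "P")), "at least 2")
})

test_that("kruskal-wallis screen flags separated features, not constant ones", {
  withr::with_seed(91, {
    n <- 20
    v <- matrix(0, n, 3)
    v[, 1] <- c(runif(10, 0.01, 0.05), runif(10, 0.40, 0.70))  # separated
    v[, 2] <- 0.2                                              # constant
    v[, 3] <- 1 - v[, 1] - v[, 2]                # rows sum to 1 exactly
    dimnames(v) <- list(sprintf("S%02d", 1:n), paste0("f", 1:3))
    ft <- feature_table(v, mode = "relative")
    grp <- stats::setNames(rep(c("g1", "g2"), each = 10), sample_ids(ft))
    res <- kruskal_wallis_screen(ft, grp, alpha = 0.05)
    expect_true(res$significant[res$feature_id == "f1"])
    expect_false(res$significant[res$feature_id == "f2"])
    expect_equal(res$kw_p[res$feature_id == "f2"], 1)
    expect_equal(res$direction[res$feature_id == "f1"], "under")

    # complete separation agrees with a permutation oracle
    x <- v[, 1]
    obs <- stats::kruskal.test(x, factor(grp))$statistic
    perm <- replicate(2000, {
      g <- sample(grp)
      stats::kruskal.test(x, factor(g))$statistic
    })
    p_perm <- mean(perm >= obs - 1e-12)
    expect_lt(res$kw_p[1], 0.05)
    expect_lt(p_perm, 0.05)
  })
})

test_that("screen validates groups", {
  withr::with_seed(92, {
    ft <- random_count_table(6, 4, relative = TRUE)
    grp3 <- stats::setNames(c("a", "a", "b", "b", "c", "c"), sample_ids(ft))
    expect_error(kruskal_wallis_screen(ft, grp3), "two groups")
    grp1 <- stats::setNames(c("a", rep("b", 5)), sample_ids(ft))
    expect_error(kruskal_wallis_screen(ft, grp1), "at least 2 samples")
  })
})

test_that("LDA effect size separates strong contrasts from null features", {
  withr::with_seed(101, {
    n <- 20
    v <- matrix(0, n, 3)
    v[, 1] <- c(rep(0.9, 10), rep(0.001, 10))        # huge contrast
    v[, 2] <- runif(n, 0.04, 0.05)                   # null
    v[, 3] <- 1 - v[, 1] - v[, 2]
    dimnames(v) <- list(sprintf("S%02d", 1:n), paste0("f", 1:3))
    ft <- feature_table(v, mode = "relative")
    grp <- stats::setNames(rep(c("g1", "g2"), each = 10), sample_ids(ft))
    res <- lda_effect_size(ft, grp, screened = c("f1", "f2"),
                           n_boot = 1, seed = 4)
    expect_gte(res$lda_effect[res$feature_id == "f1"], 2)
    expect_true(res$significant[res$feature_id == "f1"])
    expect_lt(res$lda_effect[res$feature_id == "f2"],
              res$lda_effect[res$feature_id == "f1"])
    expect_equal(res$direction, c("over", "under"))

    # fixed seed => identical output; bootstrap does not leak RNG state
    before <- runif(1)
    r1 <- lda_effect_size(ft, grp, c("f1", "f2"), n_boot = 10, seed = 7)
    r2 <- lda_effect_size(ft, grp, c("f1", "f2"), n_boot = 10, seed = 7)
    expect_identical(r1, r2)
  })
})

test_that("lefse_screen composes the stages and writes the res-style TSV", {
  withr::with_seed(107, {
    sim <- simulate_cohort(synthetic_config(
      n_samples = 40, n_asv_features = 50, n_otu_groups = 20,
      n_affected_features = 8, effect_log_fold = 2.5,
      depth_mean = 5000, concentration = 1, seed = 13))
    rel <- to_relative_frequency(sim$asv)
    res <- lefse_screen(rel, sim$truth$class_labels, seed = 5)
    expect_equal(nrow(res), 50)
    expect_true(all(is.na(res$lda_effect[res$kw_p >= 0.05])))
    # screened features got an effect size
    expect_true(all(!is.na(res$lda_effect[res$significant])))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_effect_report(res, path)
    back <- utils::read.table(path, sep = "\t", header = TRUE)
    expect_equal(nrow(back), 50)
    expect_named(back, c("feature_id", "direction", "kw_p", "lda_effect",
                         "significant"))
  })
})
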