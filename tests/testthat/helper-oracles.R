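# Independent oracles used to cross-check the package implementations.
# These are deliberately naive: direct formula evaluation and exhaustive
# enumeration, never calls into the code paths they verify.

# Direct evaluation of the Bray-Curtis formula with an explicit loop.
bc_oracle <- function(x, y) {
  cij <- 0
  for (f in seq_along(x)) cij <- cij + min(x[f], y[f])
  1 - 2 * cij / (sum(x) + sum(y))
}

# Exhaustive k-medoid optimum: best objective over all medoid sets.
pam_exhaustive <- function(dmat, k) {
  n <- nrow(dmat)
  best <- Inf
  best_set <- NULL
  for (set in asplit(utils::combn(n, k), 2L)) {
    obj <- sum(apply(dmat[, set, drop = FALSE], 1L, min))
    if (obj < best - 1e-12) {
      best <- obj
      best_set <- set
    }
  }
  list(objective = best, medoids = sort(best_set))
}

# Naive agglomerative clustering on a distance matrix: at each step merge
# the closest pair of clusters and record which singletons (leaves) joined,
# in sample-ID order within a step. Returns leaves in join order.
merge_order_oracle <- function(dmat, linkage = "average") {
  ids <- rownames(dmat)
  clusters <- as.list(seq_len(nrow(dmat)))
  cd <- dmat
  joined <- character(0)
  while (length(clusters) > 1L) {
    min_d <- Inf
    pair <- NULL
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters))
        if (cd[i, j] < min_d) {
          min_d <- cd[i, j]
          pair <- c(i, j)
        }
    # leaves = members of singleton clusters in this merge
    leaf_members <- unlist(clusters[pair][lengths(clusters[pair]) == 1L])
    joined <- c(joined, sort(ids[leaf_members]))
    merged <- unlist(clusters[pair])
    keep <- setdiff(seq_along(clusters), pair)
    new_cd <- matrix(0, length(keep) + 1L, length(keep) + 1L)
    for (a in seq_along(keep))
      for (b in seq_along(keep))
        new_cd[a, b] <- cd[keep[a], keep[b]]
    sizes <- lengths(clusters)
    for (a in seq_along(keep)) {
      dac <- switch(linkage,
        average = (sizes[pair[1L]] * cd[keep[a], pair[1L]] +
                   sizes[pair[2L]] * cd[keep[a], pair[2L]]) /
                  (sizes[pair[1L]] + sizes[pair[2L]]),
        complete = max(cd[keep[a], pair]),
        single = min(cd[keep[a], pair]))
      new_cd[a, length(keep) + 1L] <- dac
      new_cd[length(keep) + 1L, a] <- dac
    }
    clusters <- c(clusters[keep], list(merged))
    cd <- new_cd
  }
  joined
}

# Random count table as a feature_table, optionally converted to relative.
random_count_table <- function(n, m, relative = FALSE, max_count = 50) {
  values <- matrix(sample.int(max_count, n * m, replace = TRUE), n, m,
                   dimnames = list(sprintf("S%02d", seq_len(n)),
                                   sprintf("F%02d", seq_len(m))))
  ft <- feature_table(values, mode = "counts")
  if (relative) to_relative_frequency(ft) else ft
}

# Strictly positive random simplex vector.
random_simplex <- function(m) {
  x <- stats::rexp(m) + 1e-6
  x / sum(x)
}

# Four-sample two-class fixture with distinct opposite-centroid distances.
# Classes: S1,S2 = case; S3,S4 = control.
discriminant_fixture <- function() {
  values <- rbind(
    S1 = c(0.70, 0.20, 0.10),
    S2 = c(0.10, 0.60, 0.30),
    S3 = c(0.40, 0.40, 0.20),
    S4 = c(0.05, 0.05, 0.90))
  colnames(values) <- c("fA", "fB", "fC")
  list(table = feature_table(values, mode = "relative"),
       phenotype = impute_phenotype(
         c(S1 = "case", S2 = "case", S3 = "control", S4 = "control")))
}

# Hand/oracle-computed opposite-centroid distances for the fixture above.
discriminant_fixture_distances <- function() {
  fx <- discriminant_fixture()
  v <- fx$table$values
  cen_case <- (v["S1", ] + v["S2", ]) / 2
  cen_ctrl <- (v["S3", ] + v["S4", ]) / 2
  c(S1 = bc_oracle(v["S1", ], cen_ctrl),
    S2 = bc_oracle(v["S2", ], cen_ctrl),
    S3 = bc_oracle(v["S3", ], cen_case),
    S4 = bc_oracle(v["S4", ], cen_case))
}
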