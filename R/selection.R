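#' @title Selection results
#' @description Every selection strategy returns a `selection_result`: the
#'   ordered IDs of the `k` chosen samples together with the method name,
#'   the per-sample scores the ranking used (where the method is a ranking)
#'   and the parameters actually applied.
#' @param method method name.
#' @param k requested subsample size.
#' @param selected ordered character vector of `k` sample IDs.
#' @param scores optional named numeric vector of ranking scores.
#' @param params list of applied parameters.
#' @return an object of class `selection_result`.
#' @keywords internal
selection_result <- function(method, k, selected, scores = NULL,
                             params = list()) {
  if (anyDuplicated(selected)) stop("internal: duplicate selected samples")
  if (length(selected) != k) stop("internal: wrong selection size")
  structure(list(method = method, k = k, selected = selected,
                 scores = scores, params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s, k = %d]: %s%s\n", x$method, x$k,
              paste(utils::head(x$selected, 8L), collapse = ", "),
              if (x$k > 8L) ", ..." else ""))
  invisible(x)
}

check_selection_input <- function(table, k, min_k = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (table$mode != "relative")
    stop("selection requires a relative-frequency table; ",
         "see to_relative_frequency()")
  n <- nrow(table$values)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < min_k || k > n)
    stop("k must be an integer in [", min_k, ", ", n, "]")
  as.integer(k)
}

# Rank samples by `score` in the given direction, ties broken by sample ID
# (the package-wide tie-break: samples enumerated from lowest to highest ID).
rank_by_score <- function(ids, score, decreasing) {
  s <- if (decreasing) -score else score
  ids[order(s, ids)]
}

#' Representative subsampling (k-medoids)
#'
#' Partitions the cohort into `k` clusters by k-medoids on the Bray-Curtis
#' dissimilarity matrix and returns the `k` medoids — the samples nearest
#' the centre of each cluster — so the subsample preserves the community
#' structure of the whole cohort. Small instances (at most
#' `exhaustive_limit` candidate medoid sets) are solved exactly by
#' enumeration; larger ones use PAM (partitioning around medoids,
#' deterministic BUILD + SWAP, [cluster::pam()]). Either route is
#' deterministic; enumeration breaks objective ties by the
#' lexicographically smallest ID set.
#'
#' @param table a relative-frequency [feature_table].
#' @param k subsample size, `1 <= k <=` number of samples.
#' @param exhaustive_limit maximum number of medoid sets enumerated before
#'   falling back to the PAM heuristic.
#' @return a [selection_result]; `scores` gives each medoid's total
#'   within-cluster distance.
#' @export
select_representative <- function(table, k, exhaustive_limit = 1e4) {
  k <- check_selection_input(table, k)
  ids <- sample_ids(table)
  n <- length(ids)
  if (k == n)  # every sample is its own medoid
    return(selection_result("representative", k, sort(ids),
                            params = list(metric = "bray-curtis")))
  d <- dissimilarity_matrix(table)
  if (choose(n, k) <= exhaustive_limit) {
    dm <- as.matrix(d)
    best <- Inf
    med_idx <- NULL
    for (set in asplit(utils::combn(n, k), 2L)) {
      obj <- sum(apply(dm[, set, drop = FALSE], 1L, min))
      if (obj < best - 1e-12) {
        best <- obj
        med_idx <- set
      }
    }
    med <- ids[med_idx]
    assign_to <- med[apply(dm[, med, drop = FALSE], 1L, which.min)]
    within <- vapply(med, function(m) sum(dm[assign_to == m, m]), 0)
    return(selection_result("representative", k, med,
                            scores = stats::setNames(within, med),
                            params = list(metric = "bray-curtis",
                                          solver = "exhaustive",
                                          objective = best)))
  }
  fit <- cluster::pam(d, k = k, diss = TRUE)
  med <- fit$medoids
  within <- vapply(seq_len(k), function(j) {
    members <- ids[fit$clustering == j]
    sum(as.matrix(d)[med[j], members])
  }, 0)
  selection_result("representative", k, med,
                   scores = stats::setNames(within, med),
                   params = list(metric = "bray-curtis", solver = "pam",
                                 objective = fit$objective[["swap"]]))
}

#' Diverse subsampling (inverse Simpson ranking)
#'
#' Ranks samples by decreasing inverse Simpson index \eqn{1/\lambda} —
#' the samples carrying the most within-sample diversity — and selects the
#' top `k`. Because \eqn{1-\lambda} and \eqn{1/\lambda} are both strictly
#' decreasing in \eqn{\lambda}, either form of the Simpson index yields the
#' same ranking; selections are nested across `k`.
#'
#' @inheritParams select_representative
#' @return a [selection_result] ordered by decreasing inverse Simpson;
#'   `scores` holds the inverse Simpson indices.
#' @export
select_diverse <- function(table, k) {
  k <- check_selection_input(table, k)
  div <- diversity_table(table)
  score <- stats::setNames(div$inverse_simpson, div$sample_id)
  ranked <- rank_by_score(div$sample_id, score, decreasing = TRUE)
  selection_result("diverse", k, ranked[seq_len(k)],
                   scores = score[ranked[seq_len(k)]],
                   params = list(index = "inverse-simpson"))
}

#' Extreme subsampling (early joiners under the inverted dissimilarity)
#'
#' Inverts the Bray-Curtis matrix (as `1 - BC`, a strictly monotone
#' transform of the additive inverse that keeps distances non-negative and
#' yields the same dendrogram topology for the supported linkages) so that
#' the most mutually *dissimilar* samples become the closest pairs, builds
#' an agglomerative dendrogram, and enumerates samples in the order of the
#' merge step at which each leaf first joins another cluster. The first `k`
#' such leaves — the mutually most dissimilar, outlying samples — form the
#' subsample. Ties at a merge (two leaves joining at once) are resolved by
#' sample-ID order.
#'
#' @inheritParams select_representative
#' @param k subsample size, at least 2 (a single "most dissimilar pair"
#'   member is undefined).
#' @param linkage agglomeration rule passed to [stats::hclust()].
#' @return a [selection_result]; `scores` gives the merge height at which
#'   each selected leaf joined.
#' @export
select_extreme <- function(table, k, linkage = c("average", "complete",
                                                 "single")) {
  linkage <- match.arg(linkage)
  k <- check_selection_input(table, k, min_k = 2L)
  d <- dissimilarity_matrix(table)
  dinv <- 1 - d
  attr(dinv, "metric") <- "1 - bray-curtis"
  hc <- stats::hclust(dinv, method = linkage)
  ids <- hc$labels
  joined <- character(0)
  heights <- numeric(0)
  for (step in seq_len(nrow(hc$merge))) {
    leaves <- -hc$merge[step, ][hc$merge[step, ] < 0]
    if (length(leaves)) {
      new <- sort(ids[leaves])  # tie within one merge: sample-ID order
      joined <- c(joined, new)
      heights <- c(heights, rep(hc$height[step], length(new)))
    }
  }
  sel <- joined[seq_len(k)]
  selection_result("extreme", k, sel,
                   scores = stats::setNames(heights[seq_len(k)], sel),
                   params = list(linkage = linkage,
                                 transform = "1 - bray-curtis"))
}

#' Centroid (mean composition) of a set of samples
#'
#' @param table a [feature_table].
#' @param members non-empty character vector of sample IDs.
#' @return named numeric vector: the arithmetic mean of the members'
#'   abundance rows.
#' @export
class_centroid <- function(table, members) {
  stopifnot(inherits(table, "feature_table"))
  if (length(members) == 0L) stop("empty member set")
  missing <- setdiff(members, sample_ids(table))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  colMeans(table$values[members, , drop = FALSE])
}

# Distance of every sample to the centroid of the opposite phenotype class.
opposite_centroid_distances <- function(table, phenotype) {
  stopifnot(inherits(phenotype, "phenotype_metadata"))
  ids <- sample_ids(table)
  missing <- setdiff(ids, names(phenotype$labels))
  if (length(missing))
    stop("no phenotype for sample(s): ", paste(missing, collapse = ", "))
  lab <- phenotype$labels[ids]
  for (cls in phenotype$classes)
    if (!any(lab == cls)) stop("class '", cls, "' has no members")
  centroids <- lapply(phenotype$classes, function(cls)
    class_centroid(table, ids[lab == cls]))
  names(centroids) <- phenotype$classes
  vapply(ids, function(s) {
    other <- setdiff(phenotype$classes, lab[[s]])
    bray_curtis(table$values[s, ], centroids[[other]])
  }, 0)
}

#' Discriminant subsampling (closest to the opposite-class centroid)
#'
#' For each sample, computes the Bray-Curtis distance to the centroid
#' (mean composition) of the opposite phenotype class and selects the `k`
#' samples with the *smallest* distances, in ascending order — the samples
#' most similar to the other class, i.e. hardest to discriminate.
#'
#' @inheritParams select_representative
#' @param phenotype a `phenotype_metadata` (see [impute_phenotype()])
#'   covering every sample, with both classes non-empty.
#' @return a [selection_result] in ascending distance order; `scores` holds
#'   the centroid distances.
#' @export
select_discriminant <- function(table, phenotype, k) {
  k <- check_selection_input(table, k)
  dist <- opposite_centroid_distances(table, phenotype)
  ranked <- rank_by_score(names(dist), dist, decreasing = FALSE)
  selection_result("discriminant", k, ranked[seq_len(k)],
                   scores = dist[ranked[seq_len(k)]],
                   params = list(metric = "bray-curtis"))
}

#' Distinct subsampling (farthest from the opposite-class centroid)
#'
#' The mirror image of [select_discriminant()]: the `k` samples with the
#' *largest* Bray-Curtis distance to the opposite-class centroid, in
#' decreasing order — the samples most sharply separated from the other
#' phenotype class.
#'
#' @inheritParams select_discriminant
#' @return a [selection_result] in decreasing distance order.
#' @export
select_distinct <- function(table, phenotype, k) {
  k <- check_selection_input(table, k)
  dist <- opposite_centroid_distances(table, phenotype)
  ranked <- rank_by_score(names(dist), dist, decreasing = TRUE)
  selection_result("distinct", k, ranked[seq_len(k)],
                   scores = dist[ranked[seq_len(k)]],
                   params = list(metric = "bray-curtis"))
}

#' Principal-component scores of a feature table
#'
#' Centred (not scaled) PCA of the samples x features matrix, i.e. the
#' eigenstructure of the variance-covariance matrix. The sparse variant
#' (elastic-net regression formulation initialised from the PCA solution,
#' via [mixOmics::spca()]) constrains each component's loadings to at most
#' `keep_count` non-zero features; it is deterministic.
#'
#' @param table a [feature_table].
#' @param n_components number of components, at most
#'   `min(n_samples, n_features)`.
#' @param sparse use sparse loadings?
#' @param keep_count maximum non-zero loadings per sparse component;
#'   defaults to `max(1, ceiling(0.1 * n_features))` when `sparse = TRUE`.
#' @return an object of class `pca_model`: list with `scores` (samples x
#'   components), `loadings` (features x components),
#'   `explained_variance_fraction`, `sparse` and `keep_count`.
#' @export
pca_scores <- function(table, n_components = 2L, sparse = FALSE,
                       keep_count = NULL) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(n_samples, n_features)")
  if (all(apply(X, 2L, stats::var) < .Machine$double.eps))
    stop("degenerate table: all features have zero variance")
  if (sparse) {
    if (is.null(keep_count))
      keep_count <- max(1L, ceiling(0.1 * ncol(X)))
    keep_count <- min(as.integer(keep_count), ncol(X))
    fit <- mixOmics::spca(X, ncomp = n_components, center = TRUE,
                          scale = FALSE, keepX = rep(keep_count, n_components))
    scores <- unname(fit$variates$X)
    loadings <- unname(fit$loadings$X)
    expl <- unname(fit$prop_expl_var$X)
  } else {
    fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    scores <- unname(fit$x[, seq_len(n_components), drop = FALSE])
    loadings <- unname(fit$rotation[, seq_len(n_components), drop = FALSE])
    expl <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(n_components)]
  }
  dimnames(scores) <- list(sample_ids(table),
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(feature_ids(table),
                             paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = as.numeric(expl),
                 sparse = sparse,
                 keep_count = if (sparse) keep_count else NULL),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model (%s): %d samples, %d components; variance %s\n",
              if (x$sparse) paste0("sparse, keepX = ", x$keep_count)
              else "dense",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = " + ")))
  invisible(x)
}

# Draw the next `count` not-yet-selected IDs from an ordered queue.
take_next <- function(queue, selected, count) {
  utils::head(setdiff(queue, selected), count)
}

#' PCA / sparse-PCA extremes subsampling
#'
#' The data-driven strategy: samples with extreme coordinates on the first
#' two principal components of the (centred, unscaled) abundance matrix.
#' One third of the subsample is drawn from each extreme of PC1; the
#' remaining, not-yet-selected samples are then sorted by PC2 and one sixth
#' drawn from each PC2 extreme. A remainder (when `k` is not divisible by
#' 6) is allocated one sample at a time in the cycle PC1-top, PC1-bottom,
#' PC2-top, PC2-bottom. Ties are broken by sample-ID order; with
#' `sparse = TRUE` the identical procedure runs on sparse-PCA scores.
#'
#' @inheritParams select_representative
#' @inheritParams pca_scores
#' @return a [selection_result]; `scores` holds PC1 scores, `params`
#'   records the allocation.
#' @export
select_pca <- function(table, k, sparse = FALSE, keep_count = NULL) {
  k <- check_selection_input(table, k)
  model <- pca_scores(table, n_components = 2L, sparse = sparse,
                      keep_count = keep_count)
  ids <- sample_ids(table)
  pc1 <- model$scores[, 1L]
  pc2 <- model$scores[, 2L]
  q <- list(pc1_top = rank_by_score(ids, pc1, decreasing = TRUE),
            pc1_bottom = rank_by_score(ids, pc1, decreasing = FALSE),
            pc2_top = rank_by_score(ids, pc2, decreasing = TRUE),
            pc2_bottom = rank_by_score(ids, pc2, decreasing = FALSE))
  a <- k %/% 3L
  b <- k %/% 6L
  sel <- character(0)
  sel <- c(sel, take_next(q$pc1_top, sel, a))
  sel <- c(sel, take_next(q$pc1_bottom, sel, a))
  sel <- c(sel, take_next(q$pc2_top, sel, b))
  sel <- c(sel, take_next(q$pc2_bottom, sel, b))
  cycle <- c("pc1_top", "pc1_bottom", "pc2_top", "pc2_bottom")
  i <- 0L
  while (length(sel) < k) {
    nxt <- take_next(q[[cycle[i %% 4L + 1L]]], sel, 1L)
    sel <- c(sel, nxt)
    i <- i + 1L
  }
  method <- if (sparse) "spca" else "pca"
  selection_result(method, k, sel, scores = pc1[sel],
                   params = list(per_pc1_extreme = a, per_pc2_extreme = b,
                                 remainder = k - 2L * a - 2L * b,
                                 sparse = sparse,
                                 keep_count = model$keep_count,
                                 explained_variance_fraction =
                                   model$explained_variance_fraction))
}

#' Dispatch a selection method by name
#'
#' @param table a relative-frequency [feature_table].
#' @param method one of `"representative"`, `"diverse"`, `"extreme"`,
#'   `"discriminant"`, `"distinct"`, `"pca"`, `"spca"`.
#' @param k subsample size.
#' @param phenotype required for `"discriminant"` and `"distinct"`.
#' @param linkage for `"extreme"`; see [select_extreme()].
#' @param keep_count for `"spca"`; see [pca_scores()].
#' @return a [selection_result].
#' @export
select_subsample <- function(table, method, k, phenotype = NULL,
                             linkage = NULL, keep_count = NULL) {
  method <- match.arg(method, selection_methods())
  switch(method,
    representative = select_representative(table, k),
    diverse = select_diverse(table, k),
    extreme = if (is.null(linkage)) select_extreme(table, k)
              else select_extreme(table, k, linkage = linkage),
    discriminant = select_discriminant(table, phenotype, k),
    distinct = select_distinct(table, phenotype, k),
    pca = select_pca(table, k, sparse = FALSE),
    spca = select_pca(table, k, sparse = TRUE, keep_count = keep_count))
}

#' @rdname select_subsample
#' @export
selection_methods <- function() {
  c("representative", "diverse", "extreme", "discriminant", "distinct",
    "pca", "spca")
}
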