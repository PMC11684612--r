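#' Pairwise agreement between two selections
#'
#' Overlap fraction and UpSet-style exclusive intersections for two
#' selections drawn from one sample universe, e.g. the same method applied
#' to the ASV and the OTU table.
#'
#' @param a,b [selection_result] objects (or plain character vectors of
#'   sample IDs).
#' @return an `agreement_report`: list with `set_sizes`, `intersections`
#'   (exclusive: `both`, `only_a`, `only_b`), `overlap_fraction`
#'   (`|A ∩ B| / k` for equal sizes, `|A ∩ B| / max(kA, kB)` otherwise)
#'   and `size_mismatch`.
#' @export
pairwise_overlap <- function(a, b) {
  sa <- selected_ids(a)
  sb <- selected_ids(b)
  inter <- length(intersect(sa, sb))
  mismatch <- length(sa) != length(sb)
  structure(list(
    set_sizes = c(a = length(sa), b = length(sb)),
    intersections = c(both = inter,
                      only_a = length(sa) - inter,
                      only_b = length(sb) - inter),
    overlap_fraction = inter / max(length(sa), length(sb)),
    size_mismatch = mismatch),
    class = "agreement_report")
}

selected_ids <- function(x) {
  if (inherits(x, "selection_result")) x$selected else as.character(x)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement_report: overlap %.1f%% (%s)\n",
              100 * x$overlap_fraction,
              paste(sprintf("%s=%d", names(x$intersections), x$intersections),
                    collapse = ", ")))
  invisible(x)
}

#' UpSet-style exclusive intersection counts
#'
#' For two or more selections over one universe, counts for every
#' membership pattern (which selections contain a sample) the number of
#' samples showing exactly that pattern. These exclusive counts partition
#' the union — the quantities an UpSet plot displays.
#'
#' @param selections named list of [selection_result] objects or ID
#'   vectors; unnamed lists are labelled `set1, set2, ...`.
#' @return an `upset_report`: list with `set_sizes` (named integer) and
#'   `intersections`, a `data.frame` with one row per non-empty pattern
#'   (`pattern` = labels joined by `&`, `count`), sorted by decreasing
#'   count then pattern.
#' @export
upset_counts <- function(selections) {
  if (length(selections) < 2L) stop("need at least 2 selections")
  if (is.null(names(selections)) || any(!nzchar(names(selections))))
    names(selections) <- paste0("set", seq_along(selections))
  sets <- lapply(selections, selected_ids)
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  df <- data.frame(pattern = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(set_sizes = vapply(sets, length, 0L),
                 intersections = df),
            class = "upset_report")
}

#' @export
print.upset_report <- function(x, ...) {
  cat("upset_report:\n")
  print(x$intersections)
  invisible(x)
}

#' Kruskal-Wallis differential-abundance screen
#'
#' Per-feature Kruskal-Wallis rank-sum test (tie-corrected chi-square
#' approximation, 1 df for two groups) between two groups of samples, e.g.
#' selected vs unselected or case vs control. Following the LEfSe
#' convention, no multiple-testing correction is applied by default.
#'
#' @param table a relative-frequency [feature_table].
#' @param groups named character vector mapping every sample of `table` to
#'   one of exactly two group labels; each group needs at least 2 samples.
#' @param alpha significance level (default 0.05).
#' @param group_of_interest which group "over"/"under" directions refer to;
#'   defaults to the first group label in sorted order.
#' @param adjust apply Benjamini-Hochberg correction before thresholding?
#' @return a `data.frame` with one row per feature: `feature_id`, `kw_p`,
#'   `direction` (`"over"`/`"under"` in the group of interest),
#'   `significant`.
#' @export
kruskal_wallis_screen <- function(table, groups, alpha = 0.05,
                                  group_of_interest = NULL, adjust = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (table$mode != "relative")
    stop("screen requires a relative-frequency table")
  ids <- sample_ids(table)
  missing <- setdiff(ids, names(groups))
  if (length(missing))
    stop("no group for sample(s): ", paste(missing, collapse = ", "))
  g <- factor(groups[ids])
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  if (is.null(group_of_interest)) group_of_interest <- levels(g)[1L]
  if (!group_of_interest %in% levels(g))
    stop("group_of_interest not among the group labels")
  in_grp <- g == group_of_interest
  res <- vapply(seq_len(ncol(table$values)), function(j) {
    x <- table$values[, j]
    p <- if (length(unique(x)) == 1L) 1  # constant feature: no evidence
         else stats::kruskal.test(x, g)$p.value
    c(p = p, delta = mean(x[in_grp]) - mean(x[!in_grp]))
  }, c(p = 0, delta = 0))
  p <- res["p", ]
  p_used <- if (adjust) stats::p.adjust(p, "BH") else p
  data.frame(feature_id = feature_ids(table),
             kw_p = p,
             direction = ifelse(res["delta", ] >= 0, "over", "under"),
             significant = p_used < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Stratified bootstrap: 2/3 of each group's samples, with replacement,
# guaranteeing both classes are present in the resample.
boot_indices <- function(g) {
  idx <- unlist(lapply(levels(g), function(lev) {
    members <- which(g == lev)
    sample(members, size = max(1L, round(2 / 3 * length(members))),
           replace = TRUE)
  }))
  as.integer(idx)
}

#' LDA effect size for screened features
#'
#' The effect-size stage of the LEfSe procedure for a single dichotomous
#' class. Abundances are placed on LEfSe's per-million scale, and for each
#' of `n_boot` stratified bootstrap resamples (2/3 of each group) a linear
#' discriminant is fitted to the screened features; a feature's raw effect
#' in one resample is the mean of (i) the feature's coordinate of the
#' unit-norm discriminant axis scaled by the between-class separation of
#' the projected data and (ii) the absolute difference of the feature's
#' class means. The reported effect size is
#' `log10(1 + |mean over resamples|)`; a feature is significant when its
#' Kruskal-Wallis p-value passed the screen and the effect size reaches
#' `threshold` (default 2.0, the LEfSe convention).
#'
#' @param table a relative-frequency [feature_table].
#' @param groups named character vector, sample -> one of two groups.
#' @param screened character vector of feature IDs that passed
#'   [kruskal_wallis_screen()] (non-empty).
#' @param n_boot bootstrap resamples (default 30).
#' @param seed integer seed making the bootstrap reproducible.
#' @param threshold log10 effect-size threshold.
#' @param group_of_interest see [kruskal_wallis_screen()].
#' @return `data.frame`: `feature_id`, `direction`, `lda_effect`
#'   (log10 scale, `>= 0`), `significant`.
#' @export
lda_effect_size <- function(table, groups, screened, n_boot = 30L,
                            seed = 1L, threshold = 2.0,
                            group_of_interest = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (length(screened) == 0L) stop("`screened` must be non-empty")
  if (n_boot < 1L) stop("n_boot must be >= 1")
  missing <- setdiff(screened, feature_ids(table))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  ids <- sample_ids(table)
  g <- factor(groups[ids])
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (is.null(group_of_interest)) group_of_interest <- levels(g)[1L]
  X <- table$values[, screened, drop = FALSE] * 1e6  # LEfSe per-million scale
  eff <- matrix(NA_real_, n_boot, length(screened),
                dimnames = list(NULL, screened))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  for (bt in seq_len(n_boot)) {
    idx <- boot_indices(g)
    eff[bt, ] <- one_boot_effect(X[idx, , drop = FALSE], droplevels(g[idx]))
  }
  mean_eff <- colMeans(eff)
  delta <- colMeans(X[g == group_of_interest, , drop = FALSE]) -
    colMeans(X[g != group_of_interest, , drop = FALSE])
  lda_effect <- log10(1 + abs(mean_eff))
  data.frame(feature_id = screened,
             direction = ifelse(delta >= 0, "over", "under"),
             lda_effect = unname(lda_effect),
             significant = unname(lda_effect >= threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Effect of every feature in one bootstrap resample: project onto the
# unit-norm LDA axis, take the between-class separation of the projection,
# and average the axis-scaled coordinate with the raw class-mean gap.
one_boot_effect <- function(Xb, gb) {
  keep <- apply(Xb, 2L, function(col) stats::sd(col) > 0)
  w <- numeric(ncol(Xb))
  if (any(keep)) {
    fit <- tryCatch(
      suppressWarnings(MASS::lda(Xb[, keep, drop = FALSE], grouping = gb,
                                 tol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      wk <- fit$scaling[, 1L]
      wk <- wk / sqrt(sum(wk^2))
      proj <- Xb[, keep, drop = FALSE] %*% wk
      sep <- abs(mean(proj[gb == levels(gb)[1L]]) -
                 mean(proj[gb == levels(gb)[2L]]))
      w[keep] <- abs(wk) * sep
    }
  }
  gap <- abs(colMeans(Xb[gb == levels(gb)[1L], , drop = FALSE]) -
             colMeans(Xb[gb == levels(gb)[2L], , drop = FALSE]))
  (w + gap) / 2
}

#' Run the full LEfSe-style screen
#'
#' Convenience wrapper: Kruskal-Wallis screen at `alpha`, then LDA effect
#' sizes for the features that passed. Features failing the screen are
#' reported with `lda_effect = NA` and `significant = FALSE`.
#'
#' @inheritParams lda_effect_size
#' @inheritParams kruskal_wallis_screen
#' @return `data.frame` with columns `feature_id`, `kw_p`, `direction`,
#'   `lda_effect`, `significant` (one row per feature of the table).
#' @export
lefse_screen <- function(table, groups, alpha = 0.05, n_boot = 30L,
                         seed = 1L, threshold = 2.0,
                         group_of_interest = NULL, adjust = FALSE) {
  kw <- kruskal_wallis_screen(table, groups, alpha = alpha,
                              group_of_interest = group_of_interest,
                              adjust = adjust)
  kw$lda_effect <- NA_real_
  passed <- kw$feature_id[kw$significant]
  kw$significant <- FALSE
  if (length(passed)) {
    lda <- lda_effect_size(table, groups, passed, n_boot = n_boot,
                           seed = seed, threshold = threshold,
                           group_of_interest = group_of_interest)
    m <- match(lda$feature_id, kw$feature_id)
    kw$lda_effect[m] <- lda$lda_effect
    kw$direction[m] <- lda$direction
    kw$significant[m] <- lda$significant
  }
  kw
}

#' Write an effect-size report as TSV
#'
#' Mirrors LEfSe's `res` output layout: one feature per row with columns
#' `feature_id`, `direction`, `kw_p`, `lda_effect`, `significant`.
#'
#' @param report a `data.frame` from [lefse_screen()] or
#'   [kruskal_wallis_screen()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effect_report <- function(report, path) {
  cols <- intersect(c("feature_id", "direction", "kw_p", "lda_effect",
                      "significant"), names(report))
  out <- report[cols]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.6g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
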