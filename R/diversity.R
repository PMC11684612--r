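#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \deqn{BC_{ij} = 1 - \frac{2 C_{ij}}{S_i + S_j}}
#' where \eqn{C_{ij} = \sum_f \min(x_f, y_f)} is the shared abundance and
#' \eqn{S_i}, \eqn{S_j} are the total abundances of the two samples. Ranges
#' from 0 (identical composition) to 1 (no shared features).
#'
#' @param x,y non-negative numeric vectors of equal length, each with a
#'   positive sum. Counts and relative frequencies are both valid.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(6, 2), c(2, 2))  # 1 - 8/12 = 1/3
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors differ in length (", length(x), " vs ", length(y), ")")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  si <- sum(x); sj <- sum(y)
  if (si <= 0 || sj <= 0) stop("all-zero abundance vector")
  1 - 2 * sum(pmin(x, y)) / (si + sj)
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' Beta diversity between every pair of samples of a feature table,
#' computed with [vegan::vegdist()].
#'
#' @param table a [feature_table] with at least two samples, each with a
#'   positive total.
#' @return a [stats::dist] object labelled by sample ID, with attribute
#'   `metric = "bray-curtis"`.
#' @export
dissimilarity_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2L) stop("need at least 2 samples")
  totals <- rowSums(table$values)
  if (any(totals <= 0))
    stop("sample(s) with zero total: ",
         paste(sample_ids(table)[totals <= 0], collapse = ", "))
  d <- vegan::vegdist(table$values, method = "bray")
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Simpson-family alpha-diversity profile of one sample
#'
#' For relative frequencies \eqn{p_f} the Simpson concentration is
#' \eqn{\lambda = \sum_f p_f^2}; the Gini-Simpson index is
#' \eqn{D = 1 - \lambda} and the inverse Simpson index \eqn{1/\lambda}.
#' For raw counts \eqn{k_f} with total \eqn{K} the finite-sample
#' (unbiased) form is used:
#' \deqn{D = 1 - \frac{\sum_f k_f (k_f - 1)}{K (K - 1)}}
#' i.e. the probability that two organisms drawn without replacement belong
#' to different species.
#'
#' @param x non-negative abundance vector with positive sum; integer-valued
#'   when `mode = "counts"`.
#' @param mode `"counts"` or `"relative"`.
#' @return a one-row `data.frame` with columns `simpson_lambda`,
#'   `gini_simpson`, `inverse_simpson` and `shannon` (natural log).
#' @examples
#' simpson_profile(c(2, 2), mode = "counts")    # D = 1 - 4/12 = 2/3
#' simpson_profile(c(0.5, 0.5), mode = "relative")
#' @export
simpson_profile <- function(x, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (any(x < 0)) stop("abundances must be non-negative")
  K <- sum(x)
  if (K <= 0) stop("all-zero abundance vector")
  if (mode == "counts") {
    if (any(abs(x - round(x)) > 1e-8))
      stop("counts mode requires integer abundances")
    if (K < 2) stop("counts mode needs a total of at least 2 organisms")
    lambda <- sum(x * (x - 1)) / (K * (K - 1))
  } else {
    p <- x / K
    lambda <- sum(p^2)
  }
  data.frame(simpson_lambda = lambda,
             gini_simpson = 1 - lambda,
             inverse_simpson = 1 / lambda,
             shannon = shannon(x))
}

#' Shannon diversity of an abundance vector
#'
#' \eqn{H = -\sum_f p_f \log p_f} over positive proportions, with
#' \eqn{0 \log 0 = 0}.
#'
#' @param x non-negative abundance vector with positive sum.
#' @param base logarithm base; natural log by default.
#' @return Shannon index, `>= 0`.
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("all-zero abundance vector")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Per-sample diversity summary for a feature table
#'
#' Applies [simpson_profile()] to every sample row; counts tables use the
#' finite-sample Simpson form, relative tables the `sum(p^2)` form.
#'
#' @param table a [feature_table].
#' @return a `data.frame` with one row per sample (`sample_id` column plus
#'   the [simpson_profile()] columns), in table order.
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  rows <- lapply(seq_len(nrow(table$values)), function(i)
    simpson_profile(table$values[i, ], mode = table$mode))
  out <- do.call(rbind, rows)
  cbind(data.frame(sample_id = sample_ids(table), stringsAsFactors = FALSE),
        out, row.names = NULL)
}

#' Write / read a square dissimilarity matrix as TSV
#'
#' lsmat-style layout: header row and first column carry the sample IDs.
#'
#' @param d a [stats::dist] object with labels.
#' @param path file path.
#' @return `path` (writer) or a `dist` object (reader).
#' @export
write_dissimilarity <- function(d, path) {
  m <- as.matrix(d)
  lines <- c(paste(c("", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
    stop("matrix in ", path, " is not symmetric")
  d <- stats::as.dist(m)
  attr(d, "metric") <- "bray-curtis"
  d
}
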