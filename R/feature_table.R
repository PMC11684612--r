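#' Construct a feature table
#'
#' A feature table holds a samples x features abundance matrix, either raw
#' counts or relative frequencies, with optional taxonomy strings per
#' feature. It is the common currency of every selection strategy in the
#' package: diversity metrics, dissimilarity matrices and the selection
#' methods all consume one.
#'
#' @param values numeric matrix, samples in rows and features in columns,
#'   with unique non-empty row and column names. All entries must be
#'   non-negative and finite.
#' @param mode `"counts"` or `"relative"`. When `NULL` (default) the mode is
#'   inferred: `"relative"` if every row sums to 1 within `1e-6`, otherwise
#'   `"counts"`.
#' @param taxonomy optional named character vector mapping feature IDs to
#'   semicolon-delimited taxonomy strings (e.g.
#'   `"Bacteria;Firmicutes;Clostridia"`). Names must cover a subset of the
#'   feature IDs.
#' @return an object of class `feature_table`: a list with elements
#'   `values`, `mode` and `taxonomy`.
#' @examples
#' m <- matrix(c(4, 6, 0, 2, 2, 6), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), c("fA", "fB")))
#' ft <- feature_table(m)
#' ft$mode
#' @export
feature_table <- function(values, mode = NULL, taxonomy = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("feature table is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample IDs as rownames and feature IDs as colnames")
  dup_s <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_s))
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_f))
    stop("duplicate feature ID(s): ", paste(dup_f, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature table contains missing or non-finite values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (is.null(mode)) {
    rs <- rowSums(values)
    mode <- if (all(abs(rs - 1) <= 1e-6)) "relative" else "counts"
  }
  mode <- match.arg(mode, c("counts", "relative"))
  if (mode == "relative" && any(abs(rowSums(values) - 1) > 1e-6))
    stop("mode = 'relative' but some sample rows do not sum to 1")
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !all(names(taxonomy) %in% colnames(values)))
      stop("taxonomy names must be feature IDs of the table")
    taxonomy <- taxonomy[intersect(colnames(values), names(taxonomy))]
  }
  structure(list(values = values, mode = mode, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s%s)\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Sample and feature identifiers of a feature table
#' @param table a [feature_table]
#' @return character vector of IDs, in table order.
#' @export
sample_ids <- function(table) rownames(table$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(table) colnames(table$values)

#' Read a feature table from disk
#'
#' Reads tab-separated feature tables in the QIIME/BIOM text convention
#' (features as rows, samples as columns, first header cell `#FeatureID`,
#' optional trailing `Taxonomy` column) or BIOM JSON (format 1.0, via the
#' \pkg{biomformat} package). Orientation is normalised to samples x
#' features regardless of the on-disk layout.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param orientation for TSV input, whether rows of the file are
#'   `"features"` (default, the ecosystem convention) or `"samples"`.
#' @return a [feature_table]; `mode` is inferred from the row sums.
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, format = c("tsv", "biom"),
                               orientation = c("features", "samples")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")   # features x samples
    tax <- tryCatch({
      om <- biomformat::observation_metadata(b)
      if (is.null(om) || (is.data.frame(om) && all(is.na(om)))) NULL
      else if (is.data.frame(om))
        stats::setNames(apply(om, 1L, paste, collapse = ";"), rownames(om))
      else stats::setNames(vapply(om, paste, "", collapse = ";"), names(om))
    }, error = function(e) NULL)
    return(feature_table(t(m), taxonomy = tax))
  }
  first <- readLines(path, n = 1L)
  header <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "",
                          colClasses = "character", skip = 0L)
  names(df)[1L] <- sub("^#", "", header[1L])
  ids <- df[[1L]]
  tax <- NULL
  tax_col <- which(tolower(names(df)) == "taxonomy")
  if (length(tax_col)) {
    tax <- stats::setNames(df[[tax_col[1L]]], ids)
    df <- df[-tax_col[1L]]
  }
  num <- as.matrix(df[-1L])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) stop("non-numeric or missing abundance values in ", path)
  rownames(num) <- ids
  if (orientation == "features") {
    m <- t(num)
  } else {
    m <- num
    tax <- NULL  # taxonomy column only meaningful with features as rows
  }
  feature_table(m, taxonomy = tax)
}

#' Write a feature table as TSV
#'
#' Writes the features-as-rows TSV dialect read by [read_feature_table()].
#' Values are written with `%.17g` so a write/read cycle reproduces the
#' numbers bit-exactly.
#'
#' @param table a [feature_table]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  m <- t(table$values)  # features x samples
  lines <- character(nrow(m) + 1L)
  header <- c("#FeatureID", colnames(m))
  has_tax <- !is.null(table$taxonomy)
  if (has_tax) header <- c(header, "Taxonomy")
  lines[1L] <- paste(header, collapse = "\t")
  for (i in seq_len(nrow(m))) {
    row <- c(rownames(m)[i], sprintf("%.17g", m[i, ]))
    if (has_tax) row <- c(row, as.character(table$taxonomy[rownames(m)[i]]))
    lines[i + 1L] <- paste(row, collapse = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert counts to relative frequencies
#'
#' Divides the count of each clade in a sample by the total count of all
#' clades in that sample, so every sample row sums to 1. Already-relative
#' tables are returned unchanged.
#'
#' @param table a [feature_table]
#' @return a [feature_table] with `mode = "relative"`.
#' @export
to_relative_frequency <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$mode == "relative") return(table)
  totals <- rowSums(table$values)
  if (any(totals <= 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(table$values)[totals <= 0], collapse = ", "))
  feature_table(table$values / totals, mode = "relative",
                taxonomy = table$taxonomy)
}

# Strip one-letter rank prefixes ("k__", "g__", ...) and whitespace from the
# split taxonomy ranks so Silva- and Greengenes-style strings compare equal.
clean_ranks <- function(tax_string) {
  ranks <- strsplit(tax_string, ";", fixed = TRUE)[[1L]]
  ranks <- sub("^\\s*[a-zA-Z]__", "", trimws(ranks))
  ranks
}

#' Collapse features sharing a taxonomy prefix
#'
#' Sums all features whose taxonomy strings are identical when truncated at
#' `rank` levels into a single feature named by that prefix, e.g. collapsing
#' ASVs into taxon-level OTU-like groups. Per-sample totals are conserved
#' exactly.
#'
#' @param table a [feature_table] with taxonomy for every feature.
#' @param rank positive integer: number of leading taxonomy ranks to keep.
#' @return a [feature_table] whose features are the distinct truncated
#'   taxonomies, in order of first appearance.
#' @export
collapse_taxonomy <- function(table, rank) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(rank) || length(rank) != 1L || rank < 1)
    stop("`rank` must be a positive integer")
  missing_tax <- setdiff(feature_ids(table), names(table$taxonomy))
  if (length(missing_tax))
    stop("missing taxonomy for feature(s): ",
         paste(missing_tax, collapse = ", "))
  keys <- vapply(feature_ids(table), function(f) {
    ranks <- clean_ranks(table$taxonomy[[f]])
    paste(utils::head(ranks, rank), collapse = ";")
  }, "")
  groups <- unique(keys)
  out <- matrix(0, nrow(table$values), length(groups),
                dimnames = list(sample_ids(table), groups))
  for (g in groups)
    out[, g] <- rowSums(table$values[, keys == g, drop = FALSE])
  feature_table(out, mode = table$mode,
                taxonomy = stats::setNames(groups, groups))
}

#' Impute missing phenotype labels
#'
#' Applies the missing-value rule for a dichotomous phenotype: samples
#' without a recorded label are assigned the reference class (by default
#' `"control"`, i.e. no known condition). The set of imputed samples is
#' recorded.
#'
#' @param raw_labels named character vector, sample ID -> class label;
#'   `NA` or empty string marks a missing label.
#' @param reference_class label assigned to missing entries.
#' @param classes the two-class alphabet.
#' @return an object of class `phenotype_metadata`: list with `labels`
#'   (named character, complete), `imputed` (character vector of sample IDs)
#'   and `classes`.
#' @export
impute_phenotype <- function(raw_labels, reference_class = "control",
                             classes = c("case", "control")) {
  if (length(classes) != 2L) stop("exactly two classes are required")
  if (!reference_class %in% classes)
    stop("reference_class must be one of: ", paste(classes, collapse = ", "))
  if (is.null(names(raw_labels)) || any(!nzchar(names(raw_labels))))
    stop("`raw_labels` must be named by sample ID")
  lab <- as.character(raw_labels)
  missing <- is.na(lab) | !nzchar(lab)
  bad <- unique(lab[!missing & !lab %in% classes])
  if (length(bad))
    stop("label(s) outside the class alphabet: ", paste(bad, collapse = ", "))
  lab[missing] <- reference_class
  structure(list(labels = stats::setNames(lab, names(raw_labels)),
                 imputed = names(raw_labels)[missing],
                 classes = classes),
            class = "phenotype_metadata")
}

#' @export
print.phenotype_metadata <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$classes))
  cat(sprintf("phenotype_metadata: %d samples (%s), %d imputed\n",
              length(x$labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$imputed)))
  invisible(x)
}

#' Read phenotype metadata from TSV
#'
#' Expects columns `sample_id` and `phenotype`; empty or NA cells mark a
#' missing label, filled by [impute_phenotype()].
#'
#' @inheritParams impute_phenotype
#' @param path TSV file path.
#' @return a `phenotype_metadata` object.
#' @export
read_phenotype <- function(path, reference_class = "control",
                           classes = c("case", "control")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = c("NA", ""))
  need <- c("sample_id", "phenotype")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  impute_phenotype(stats::setNames(df$phenotype, df$sample_id),
                   reference_class = reference_class, classes = classes)
}
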