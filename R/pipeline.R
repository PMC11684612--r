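#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]: which tables to process,
#' which selection methods at which subsample sizes, and the statistical
#' parameters of the differential-representation screen.
#'
#' @param asv_table,otu_table [feature_table] objects or TSV paths readable
#'   by [read_feature_table()]. `otu_table` may be `NULL` to run on a
#'   single table.
#' @param metadata `phenotype_metadata`, a TSV path for [read_phenotype()],
#'   or `NULL` (phenotype-aware methods then unavailable).
#' @param methods subset of [selection_methods()].
#' @param sizes subsample sizes; default `c(20, 50, 100)`, truncated to the
#'   cohort size.
#' @param outdir output directory, created if needed.
#' @param seed integer seed for the effect-size bootstrap.
#' @param linkage,keep_count,n_boot,alpha,threshold method parameters, see
#'   [select_extreme()], [pca_scores()] and [lefse_screen()].
#' @param screen run the selected-vs-unselected LEfSe-style screen for each
#'   selection?
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(asv_table, otu_table = NULL, metadata = NULL,
                            methods = selection_methods(),
                            sizes = c(20L, 50L, 100L),
                            outdir = "micropick_out", seed = 1L,
                            linkage = "average", keep_count = NULL,
                            n_boot = 30L, alpha = 0.05, threshold = 2.0,
                            screen = TRUE) {
  methods <- match.arg(methods, selection_methods(), several.ok = TRUE)
  if (any(sizes < 1L)) stop("sizes must be positive")
  structure(list(asv_table = asv_table, otu_table = otu_table,
                 metadata = metadata, methods = methods,
                 sizes = as.integer(sort(unique(sizes))), outdir = outdir,
                 seed = as.integer(seed), linkage = linkage,
                 keep_count = keep_count, n_boot = as.integer(n_boot),
                 alpha = alpha, threshold = threshold, screen = screen),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; table and metadata
#' entries are file paths resolved relative to the YAML file.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
                         else file.path(base, p)
  args <- y
  for (key in c("asv_table", "otu_table", "metadata"))
    if (!is.null(y[[key]])) args[[key]] <- resolve(y[[key]])
  do.call(pipeline_config, args)
}

as_table <- function(x, orientation = "features") {
  if (is.null(x)) return(NULL)
  t <- if (inherits(x, "feature_table")) x
       else read_feature_table(x, orientation = orientation)
  to_relative_frequency(t)
}

write_selection_files <- function(sel, dir, label) {
  ids_path <- file.path(dir, paste0(label, "_selection.txt"))
  writeLines(sel$selected, ids_path)
  json_path <- file.path(dir, paste0(label, "_selection.json"))
  jsonlite::write_json(
    list(method = sel$method, k = sel$k, selected = sel$selected,
         scores = as.list(sel$scores), params = sel$params),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(ids_path, json_path)
}

#' Run the selection pipeline
#'
#' Orchestrates the full workflow on one or two (ASV and OTU) feature
#' tables: relative-frequency normalisation, every requested selection
#' method at every size, ASV-vs-OTU agreement per method and size, and an
#' optional selected-vs-unselected differential-representation screen per
#' selection. Outputs land under `outdir/{method}/{size}/`; a JSON
#' manifest records the configuration hash, seed, package version and
#' per-stage status. Rerunning with an identical configuration and seed
#' reproduces the selection outputs byte for byte.
#'
#' @param config a [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @param quiet suppress per-stage log lines on stderr?
#' @return the manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  tables <- list(asv = as_table(config$asv_table),
                 otu = as_table(config$otu_table))
  tables <- Filter(Negate(is.null), tables)
  phen <- config$metadata
  if (is.character(phen)) phen <- read_phenotype(phen)
  needs_phen <- intersect(config$methods, c("discriminant", "distinct"))
  if (length(needs_phen) && is.null(phen))
    stop("methods ", paste(needs_phen, collapse = ", "),
         " require phenotype metadata")
  n_min <- min(vapply(tables, function(t) nrow(t$values), 0L))
  if (any(config$sizes > n_min))
    stop("sizes exceed the cohort size (", n_min, "): ",
         paste(config$sizes[config$sizes > n_min], collapse = ", "))

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  stages <- list()
  note <- function(stage, status, outputs, elapsed) {
    line <- sprintf("[%s] %s: %s (%.2fs) -> %s", status, stage,
                    if (status == "ok") "done" else status, elapsed,
                    paste(basename(outputs), collapse = ", "))
    writeLines(line, log_con)
    if (!quiet) message(line)
    stages[[length(stages) + 1L]] <<-
      list(stage = stage, status = status,
           outputs = as.list(outputs), seconds = round(elapsed, 3))
  }
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      note(stage, paste0("error: ", conditionMessage(res)), character(0),
           elapsed)
      NULL
    } else {
      note(stage, "ok", res$outputs, elapsed)
      res$value
    }
  }

  selections <- list()
  for (method in config$methods) {
    for (size in config$sizes) {
      stage_dir <- file.path(config$outdir, method, size)
      dir.create(stage_dir, recursive = TRUE, showWarnings = FALSE)
      for (label in names(tables)) {
        key <- paste(method, size, label, sep = "/")
        sel <- run_stage(paste0("select:", key), function() {
          s <- select_subsample(
            tables[[label]], method, size, phenotype = phen,
            linkage = if (method == "extreme") config$linkage else NULL,
            keep_count = if (method %in% c("pca", "spca"))
              config$keep_count else NULL)
          list(value = s, outputs = write_selection_files(s, stage_dir, label))
        })
        if (!is.null(sel)) selections[[key]] <- sel
      }
      if (length(tables) == 2L) {
        a <- selections[[paste(method, size, "asv", sep = "/")]]
        b <- selections[[paste(method, size, "otu", sep = "/")]]
        if (!is.null(a) && !is.null(b)) {
          run_stage(paste0("agree:", method, "/", size), function() {
            rep <- pairwise_overlap(a, b)
            p <- file.path(stage_dir, "agreement.json")
            jsonlite::write_json(
              list(method = method, k = size,
                   overlap_fraction = rep$overlap_fraction,
                   set_sizes = as.list(rep$set_sizes),
                   intersections = as.list(rep$intersections)),
              p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
            list(value = rep, outputs = p)
          })
        }
      }
      if (config$screen) {
        for (label in names(tables)) {
          sel <- selections[[paste(method, size, label, sep = "/")]]
          if (is.null(sel)) next
          tbl <- tables[[label]]
          grp <- ifelse(sample_ids(tbl) %in% sel$selected,
                        "selected", "unselected")
          names(grp) <- sample_ids(tbl)
          if (min(table(grp)) < 2L) next  # degenerate contrast
          run_stage(paste0("screen:", method, "/", size, "/", label),
                    function() {
            rep <- lefse_screen(tbl, grp, alpha = config$alpha,
                                n_boot = config$n_boot, seed = config$seed,
                                threshold = config$threshold,
                                group_of_interest = "selected")
            p <- file.path(stage_dir, paste0(label, "_effect_sizes.tsv"))
            write_effect_report(rep, p)
            list(value = rep, outputs = p)
          })
        }
      }
    }
  }

  cfg_for_hash <- config
  cfg_for_hash$asv_table <- NULL; cfg_for_hash$otu_table <- NULL
  cfg_for_hash$metadata <- NULL
  tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(unclass(cfg_for_hash), auto_unbox = TRUE,
                              null = "null"), tmp)
  manifest <- list(
    package = "micropick",
    version = as.character(utils::packageVersion("micropick")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    methods = config$methods, sizes = config$sizes,
    tables = names(tables),
    stages = stages)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  failed <- vapply(stages, function(s) s$status != "ok", TRUE)
  if (any(failed))
    warning(sum(failed), " pipeline stage(s) failed; see manifest")
  invisible(manifest)
}
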