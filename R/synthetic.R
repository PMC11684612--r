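#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror a realistic infant-gut 16S cohort: 199 samples, 326
#' ASV-level features merged many-to-one into 160 coarser OTU-like groups,
#' 30% of subjects in the case class, Dirichlet base compositions sparse
#' enough to give Shannon diversities around 1.9, and negative-binomial
#' sequencing depths around 50,000 reads.
#'
#' @param n_samples number of samples.
#' @param n_asv_features number of fine-grained (ASV-like) features.
#' @param n_otu_groups number of merged (OTU-like) groups,
#'   `<= n_asv_features`.
#' @param class_fraction fraction of samples in the case class, in (0, 1).
#' @param n_affected_features number of features whose mean abundance
#'   differs between classes.
#' @param effect_log_fold natural-log fold change applied (with random
#'   sign) to affected features in the case class; 0 disables the effect.
#' @param depth_mean,depth_dispersion mean and dispersion (`size`) of the
#'   negative-binomial per-sample sequencing depth.
#' @param concentration symmetric Dirichlet parameter for the base
#'   composition; smaller values give sparser, lower-diversity communities.
#' @param granularity_noise fraction of each sample's reads reassigned at
#'   random between OTU groups after merging (split/merge noise emulating
#'   ASV/OTU clustering disagreement); 0 (the default) keeps the OTU table
#'   an exact column-group sum of the ASV table.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 199L, n_asv_features = 326L,
                             n_otu_groups = 160L, class_fraction = 0.3,
                             n_affected_features = 20L, effect_log_fold = 1,
                             depth_mean = 5e4, depth_dispersion = 5,
                             concentration = 0.01, granularity_noise = 0,
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_asv_features = as.integer(n_asv_features),
              n_otu_groups = as.integer(n_otu_groups),
              class_fraction = class_fraction,
              n_affected_features = as.integer(n_affected_features),
              effect_log_fold = effect_log_fold,
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              concentration = concentration,
              granularity_noise = granularity_noise,
              seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 4L) stop("n_samples must be at least 4")
    if (n_otu_groups > n_asv_features)
      stop("n_otu_groups must not exceed n_asv_features")
    if (n_affected_features > n_asv_features)
      stop("n_affected_features must not exceed n_asv_features")
    if (class_fraction <= 0 || class_fraction >= 1)
      stop("class_fraction must lie in (0, 1)")
    if (effect_log_fold < 0) stop("effect_log_fold must be >= 0")
    if (depth_mean <= 0 || depth_dispersion <= 0 || concentration <= 0)
      stop("depth_mean, depth_dispersion and concentration must be positive")
    if (granularity_noise < 0 || granularity_noise >= 1)
      stop("granularity_noise must lie in [0, 1)")
  })
  structure(cfg, class = "synthetic_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # guard against underflow
  g / sum(g)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a paired ASV/OTU cohort with phenotype structure
#'
#' Draws one base composition per class from a symmetric
#' Dirichlet(`concentration`); in the case class the means of
#' `n_affected_features` randomly chosen features are multiplied by
#' `exp(±effect_log_fold)` (sign random per feature) and the composition
#' renormalised. Each sample receives a negative-binomial sequencing depth
#' and multinomial counts given its class composition. The OTU table is
#' the ASV table with features summed within a random many-to-one
#' ASV-to-OTU mapping (every group non-empty), emulating the coarser
#' granularity of OTU clustering; per-sample totals are conserved exactly.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `asv` and `otu` ([feature_table]s of
#'   counts), `phenotype` (`phenotype_metadata`), and `truth` (list:
#'   `affected_features` data.frame with `feature_id` and `direction`,
#'   `asv_to_otu` named character, `class_labels` named character).
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    m <- config$n_asv_features
    sample_names <- sprintf("S%03d", seq_len(n))
    asv_names <- sprintf("ASV%04d", seq_len(m))
    n_case <- max(1L, min(n - 1L, round(config$class_fraction * n)))
    labels <- stats::setNames(
      sample(c(rep("case", n_case), rep("control", n - n_case))),
      sample_names)

    base <- rdirichlet1(rep(config$concentration, m))
    affected_idx <- sort(sample.int(m, config$n_affected_features))
    sign_up <- sample(c(TRUE, FALSE), config$n_affected_features,
                      replace = TRUE)
    comp <- list(control = base, case = base)
    fold <- exp(ifelse(sign_up, 1, -1) * config$effect_log_fold)
    comp$case[affected_idx] <- comp$case[affected_idx] * fold
    comp$case <- comp$case / sum(comp$case)

    depths <- pmax(1L, stats::rnbinom(n, mu = config$depth_mean,
                                      size = config$depth_dispersion))
    counts <- t(vapply(seq_len(n), function(i)
      stats::rmultinom(1L, size = depths[i],
                       prob = comp[[labels[i]]])[, 1L],
      integer(m)))
    dimnames(counts) <- list(sample_names, asv_names)

    # many-to-one ASV -> OTU mapping with every group non-empty
    k <- config$n_otu_groups
    grp <- c(seq_len(k), sample.int(k, m - k, replace = TRUE))[sample.int(m)]
    otu_names <- sprintf("OTU%04d", seq_len(k))
    map <- stats::setNames(otu_names[grp], asv_names)
    otu_counts <- matrix(0L, n, k, dimnames = list(sample_names, otu_names))
    for (j in seq_len(k))
      otu_counts[, j] <- as.integer(rowSums(counts[, grp == j, drop = FALSE]))
    if (config$granularity_noise > 0) {
      # split/merge noise: move a fraction of each sample's reads between
      # OTU groups; per-sample totals are conserved
      for (i in seq_len(n)) {
        total <- sum(otu_counts[i, ])
        n_move <- round(config$granularity_noise * total)
        if (n_move < 1L) next
        from <- stats::rmultinom(1L, n_move,
                                 prob = otu_counts[i, ] + 1e-12)[, 1L]
        from <- pmin(from, otu_counts[i, ])
        to <- stats::rmultinom(1L, sum(from), prob = rep(1, k))[, 1L]
        otu_counts[i, ] <- otu_counts[i, ] - from + to
      }
    }

    list(asv = feature_table(counts, mode = "counts"),
         otu = feature_table(otu_counts, mode = "counts"),
         phenotype = impute_phenotype(labels),
         truth = list(
           affected_features = data.frame(
             feature_id = asv_names[affected_idx],
             direction = ifelse(sign_up, "up", "down"),
             stringsAsFactors = FALSE),
           asv_to_otu = map,
           class_labels = labels))
  })
}

#' Simulate a cohort with a planted diversity gradient
#'
#' Generates samples whose true evenness increases monotonically with
#' sample index: sample `i` draws its own composition from a symmetric
#' Dirichlet whose concentration is geometrically spaced between `low` and
#' `high` (concentration acts as a scale parameter, so even spacing on the
#' log scale gives a constant relative step). Higher concentration means a
#' more even community, hence higher inverse Simpson diversity — a harness
#' for verifying that diverse selection recovers the most even samples.
#'
#' @param config a [synthetic_config()]; `n_samples`, `n_asv_features`,
#'   depth parameters and `seed` are used.
#' @param low,high concentration bounds, `0 < low <= high`.
#' @return list with `table` (counts [feature_table]) and `concentration`
#'   (named numeric, the planted per-sample concentration).
#' @export
plant_diversity_gradient <- function(config = synthetic_config(),
                                     low = 0.05, high = 2) {
  stopifnot(inherits(config, "synthetic_config"))
  if (low <= 0 || high < low) stop("need 0 < low <= high")
  with_seed(config$seed, {
    n <- config$n_samples
    m <- config$n_asv_features
    conc <- exp(seq(log(low), log(high), length.out = n))
    sample_names <- sprintf("S%03d", seq_len(n))
    depths <- pmax(1L, stats::rnbinom(n, mu = config$depth_mean,
                                      size = config$depth_dispersion))
    counts <- t(vapply(seq_len(n), function(i) {
      p <- rdirichlet1(rep(conc[i], m))
      stats::rmultinom(1L, size = depths[i], prob = p)[, 1L]
    }, integer(m)))
    dimnames(counts) <- list(sample_names, sprintf("ASV%04d", seq_len(m)))
    list(table = feature_table(counts, mode = "counts"),
         concentration = stats::setNames(conc, sample_names))
  })
}
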