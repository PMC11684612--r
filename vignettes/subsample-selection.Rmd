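---
title: "Selecting informative subsamples for two-phase microbiome studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting informative subsamples for two-phase microbiome studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropick)
```

## The problem

Shotgun metagenomic sequencing (SM-seq) resolves microbial communities to
strain and gene level but remains expensive; 16S rRNA amplicon profiling is
cheap but coarse. A two-phase design exploits this asymmetry: profile the
whole cohort with 16S in phase 1, then use those profiles to pick a small,
informative subsample for SM-seq in phase 2. Which samples are
"informative" depends on the downstream question — preserving the cohort's
community structure, capturing its diversity extremes, or sharpening a
phenotype contrast — so micropick implements seven selection strategies
with a common interface, plus the machinery to compare what they choose
when the phase-1 features are denoised amplicon sequence variants (ASVs)
versus clustered operational taxonomic units (OTUs).

## Metrics

All strategies are driven by two classical ecology quantities computed on
relative-frequency tables (each clade count divided by its sample's total).

**Bray-Curtis dissimilarity** between samples $i$ and $j$:
$$BC_{ij} = 1 - \frac{2\sum_f \min(x_{if}, x_{jf})}{S_i + S_j},$$
with $S_i = \sum_f x_{if}$. `dissimilarity_matrix()` delegates to
`vegan::vegdist()` and the unit tests verify every entry against a direct
evaluation of the formula.

**Simpson concentration** $\lambda = \sum_f p_f^2$, reported alongside the
Gini-Simpson index $D = 1-\lambda$ and the inverse Simpson index
$1/\lambda$. For raw counts `simpson_profile()` uses the finite-sample form
$D = 1 - \sum_f k_f(k_f-1)/\big(K(K-1)\big)$ — the probability that two
organisms drawn without replacement differ in species. Whether published
Simpson values were computed on counts or proportions is often ambiguous,
so both modes are first-class; since $1-\lambda$ and $1/\lambda$ are both
strictly decreasing in $\lambda$, the choice between them never changes a
diversity *ranking*, which is all the selection uses. Shannon diversity
uses the natural log with $0\log 0 = 0$.

## The seven strategies

Given a relative table (and, for the phenotype-aware methods, a dichotomous
label), each returns an ordered set of $k$ sample IDs:

* **representative** — $k$-medoids on the Bray-Curtis matrix; the medoids
  summarise the cohort's community structure. See *Numerical choices* for
  the solver.
* **diverse** — rank by inverse Simpson, take the top $k$: the samples
  richest in within-sample diversity.
* **extreme** — invert the dissimilarity ($d' = 1 - BC$), build an
  agglomerative dendrogram, and take the first $k$ leaves to join another
  cluster. Under the inverted metric the most mutually *dissimilar*
  samples merge first, so these are the cohort's outliers.
* **discriminant / distinct** — distance of every sample to the centroid
  (mean composition) of the *opposite* phenotype class; discriminant takes
  the $k$ smallest (samples that blur the class boundary), distinct the
  $k$ largest (samples that sharpen it).
* **pca / spca** — extremes of the first two principal components of the
  centred (not scaled) abundance matrix: $\lfloor k/3\rfloor$ from each
  PC1 extreme, then $\lfloor k/6\rfloor$ from each PC2 extreme among the
  samples not yet selected, the remainder allocated one at a time cycling
  PC1-top, PC1-bottom, PC2-top, PC2-bottom. The sparse variant runs the
  identical allocation on sparse-PCA scores (`mixOmics::spca()`, loadings
  restricted to `keep_count` features, default $\lceil 0.1\,m\rceil$ of
  $m$ features — sparsity in published analyses is rarely reported, so
  the default favours interpretable components without collapsing them).

Diverse, discriminant and distinct are pure rankings, so their selections
are nested across $k$ — a property the tests assert on simulated cohorts.
Representative selection is *not* nested: medoid positions depend on the
number of clusters requested, so overlap between sizes can be low. All
methods are deterministic; ties anywhere are broken by sample-ID order
(samples are enumerated from lowest to highest ID throughout).

## Agreement analysis and the differential screen

`pairwise_overlap()` and `upset_counts()` quantify how much two or more
selections agree: exclusive intersection counts (the bars of an UpSet
plot) and the pairwise overlap fraction $|A \cap B|/k$. The exclusive
counts partition the union, which the tests verify by brute-force
membership enumeration.

`lefse_screen()` implements the two-class core of the LEfSe procedure to
ask which clades are over- or under-represented in a selection (or a
phenotype class): a per-feature Kruskal-Wallis rank test at
$\alpha = 0.05$ with no multiple-testing correction (the LEfSe default; a
`adjust = TRUE` flag enables Benjamini-Hochberg), followed, for features
that pass, by a bootstrap LDA effect size. LEfSe's subclass (pairwise
Wilcoxon) stage is deliberately omitted — it only matters when a subclass
covariate exists — and no cladogram rendering is attempted.

The effect size follows LEfSe's conventions: abundances on a per-million
scale; 30 stratified bootstrap resamples of 2/3 of each group; per
resample, a linear discriminant is fitted to the screened features and a
feature's raw effect is the average of its coordinate on the unit-norm LDA
axis scaled by the projected between-class separation, and its raw
class-mean gap; the reported score is $\log_{10}(1 + |\text{mean}|)$ with
the default significance threshold 2.0 (configurable — published analyses
rarely state the threshold they used). The bootstrap is seeded and restores
the caller's RNG state, so results are reproducible and side-effect free.

## The synthetic cohort generator

Real two-phase cohorts cannot be redistributed with a package, so
`simulate_cohort()` generates paired ASV/OTU tables with known ground
truth. Its defaults are the study conditions the package is exercised
under: 199 samples, 326 ASV features, 160 OTU groups, 30% cases,
negative-binomial depths around 50,000 reads (dispersion 5), and a
symmetric Dirichlet base composition with concentration 0.01 — chosen so
expected Shannon diversity is near 1.9, typical of infant-gut communities.

The generative law is deliberately simple: one base composition per class
drawn from the Dirichlet; in the case class the means of
`n_affected_features` features are multiplied by
$e^{\pm\text{effect\_log\_fold}}$ and renormalised; counts are multinomial
given each sample's composition and depth. The OTU table sums ASV columns
within a random many-to-one map with every group non-empty, so per-sample
totals are conserved exactly; an optional `granularity_noise` fraction
reassigns reads between OTU groups (conserving totals) to emulate
clustering disagreement.

What this emulates well: compositionality, depth variation, class effects
of controllable size, and the ASV-to-OTU granularity relation. What it
does not: within-class compositional overdispersion (every sample of a
class shares one composition, so between-sample variation is
multinomial-only), phylogenetic correlation between clades, and
zero-inflation beyond what sparsity induces. Consequently synthetic
selections agree between ASV and OTU tables more strongly than real
cohorts do, and passing tests demonstrate correctness of the machinery,
not field-realistic overlap levels.

`plant_diversity_gradient()` instead gives every sample its own
concentration, spaced *geometrically* between `low` and `high`
(concentration is a scale parameter, so a constant relative step is the
natural gradient); true evenness then increases monotonically with sample
index and diverse selection should recover the top-concentration samples,
which the tests check by Spearman correlation and top-$k$ recovery over
100 seeds.

## Numerical choices

* **Representative solver.** The textbook PAM heuristic (deterministic
  BUILD + SWAP) can stop in a local optimum even on four samples, because
  escaping may require two simultaneous swaps. Since the medoid set is
  *defined* as the minimiser of total within-cluster distance, instances
  with at most $10^4$ candidate sets ($\binom{n}{k}$) are solved exactly
  by enumeration (ties to the lexicographically smallest ID set); larger
  instances use `cluster::pam()`, whose BUILD+SWAP is deterministic. The
  tests verify exhaustive optimality on small instances and swap-local
  optimality generally.
* **Extreme inversion.** The dendrogram is built on $d' = 1 - BC$ rather
  than $-BC$: a strictly monotone transform that keeps distances
  non-negative (as `hclust` expects) and preserves the merge topology for
  single, complete and average linkage. Leaves are enumerated in merge
  order; two leaves joining in one step are ordered by ID.
* **Relative-mode inference.** A loaded table is treated as relative when
  every row sums to 1 within $10^{-6}$ (files printed at 6 decimals must
  round-trip); the TSV writer emits `%.17g` so write/read cycles are
  bit-exact.
* **Taxonomy comparison.** Rank prefixes (`k__`, `g__`, ...) and
  surrounding whitespace are stripped before comparing, so Silva- and
  Greengenes-style strings collapse together; the collapse rank is a
  parameter because "identical taxonomy" depends on the depth of the
  assignment.
* **Degenerate inputs.** All-zero samples, zero-total counts, single-class
  phenotypes and zero-variance tables raise errors naming the offending
  sample or feature rather than propagating NaNs; a constant feature gets
  Kruskal-Wallis $p = 1$ by convention.

## Problem sizes in the test suite

The suite exercises metric oracles on 100 random tables (≤ 12 × 20),
selection correctness on 200 exhaustive-checked instances (n ≤ 8, k ≤ 3),
nestedness on 50 simulated cohorts of 24 samples, screen calibration on
1000 null features and power on 40 planted effects at 100 samples — sizes
chosen so each scientific claim is tested at the smallest scale where it
is meaningful, keeping the whole suite under a minute on a laptop.

## A worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_samples = 60, n_asv_features = 120,
                        n_otu_groups = 50, seed = 1)
sim <- simulate_cohort(cfg)
rel <- to_relative_frequency(sim$asv)

sel <- select_representative(rel, k = 10)
sel

ov <- pairwise_overlap(
  select_diverse(rel, 20),
  select_diverse(to_relative_frequency(sim$otu), 20))
ov$overlap_fraction

res <- lefse_screen(rel, sim$truth$class_labels, seed = 1)
head(res[res$significant, ])
```

## Limitations

The package starts at the feature-table stage: no read processing,
denoising, OTU clustering or taxonomy assignment. Only Bray-Curtis beta
diversity is provided (no UniFrac — it would require a phylogeny), there
is no rarefaction, and the differential screen is the two-class LEfSe core
only. The synthetic generator's simplifications are listed above; claims
about real cohorts should be validated on real phase-1 tables, which the
I/O layer (TSV and BIOM-JSON) is designed to ingest directly.
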