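Package: micropick
Title: Subsample Selection for Two-Phase Microbiome Study Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing an informative subsample of microbiome
    samples from an amplicon (16S rRNA) feature table, for two-phase study
    designs in which cheap phase-1 amplicon profiling of a whole cohort
    guides the choice of samples sent for expensive phase-2 shotgun
    metagenomic sequencing. Implements five biologically driven selection
    strategies (representative via PAM k-medoids on Bray-Curtis
    dissimilarities, diverse via inverse Simpson ranking, extreme via
    agglomerative clustering of inverted dissimilarities, and
    phenotype-aware discriminant and distinct selection) and two
    data-driven strategies (extremes of dense and sparse principal
    components). Also provides alpha- and beta-diversity metrics,
    ASV-to-OTU feature-table handling (relative-frequency normalisation,
    taxonomic collapse, BIOM/TSV input), agreement analysis between
    selections (pairwise overlap and UpSet-style exclusive intersections),
    a Kruskal-Wallis plus LDA effect-size differential-representation
    screen, a Dirichlet-multinomial synthetic cohort generator for paired
    ASV/OTU tables, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    MASS,
    stats,
    utils,
    tools,
    vegan,
    mixOmics,
    jsonlite,
    yaml
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
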