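Package: tandemcn
Title: Copy Number of Tandem rDNA-Histone Repeats from Sequencing Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates per-haploid copy number of tandemly repeated
    rDNA-histone gene clusters from whole-genome sequencing depth, using a
    curated set of single-copy exons as the depth normalizer. Provides the
    full analysis chain: per-base coverage summaries (mean/median/mode),
    concordance-based selection of single-copy normalizer exons with
    high-copy outlier exclusion, median-ratio copy-number estimation,
    genomic-proportion estimation from mapped-read fractions, tandem
    repeat-unit architecture inference from homology-hit coordinates, and a
    comparative statistical layer (Pearson correlations, Mann-Whitney U and
    Kruskal-Wallis tests with Benjamini-Hochberg adjustment, and a Poisson
    generalized-estimating-equation regression with a phylogenetic working
    correlation). A synthetic-data module simulates references, lineage
    cohorts, per-base depth tables, read counts and trees with the
    statistical structure the estimator assumes, so the whole pipeline is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
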