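Package: hmcscape
Title: Integrative Analysis of 5-Hydroxymethylcytosine Landscapes in
    Cardiomyocyte Development and Hypertrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for integrative hydroxymethylome (hMeDIP-seq)
    analysis: replicate-consistent consensus peaks, base-level interval
    algebra, genic/promoter/intergenic annotation, RPKM/RPM coverage
    quantification (gene bodies, chromosome bins, metagene and
    anchor-centred profiles), a windowed negative-binomial exact test for
    differential hydroxymethylation, position-dependent expression
    association (Mann-Whitney contrasts, expression-quartile trends,
    histone co-marking, CpG-demethylation grouping, repeat classes),
    enhancer definition and 5-hmC stratification with nearest-gene
    expression contrasts and conservation overlap, complete-linkage and
    self-organizing-tree (SOTA) clustering with dual-evidence stage
    co-clustering, and a seeded synthetic-study generator that emulates a
    four-stage, two-replicate cardiomyocyte design with machine-readable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    IRanges,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    rtracklayer
Config/testthat/edition: 3
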