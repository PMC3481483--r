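Package: methcapr
Title: Quality Control and Group-Level Analysis of MethylCap-seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of enrichment-based DNA methylation
    sequencing (MethylCap-seq/MBD-seq) cohorts: experiment-level quality
    control (saturation analysis, CpG enrichment, CpG coverage, alignment
    rate, and a fail-two-metrics exclusion policy), fixed-width genomic
    binning of extended reads with reads-per-million scaling, feature-level
    differential methylation across two or more groups by rank-based tests
    with false discovery rate control, a per-sample Global Methylation
    Indicator summarising mean methylation signal across CpG-content
    classes, filtered hierarchical clustering with multiscale bootstrap
    support and cross-dendrogram group tracking, and export of genome
    browser tracks including discretized percentile-rank heatmap rows.
    Includes a seeded simulator of CpG-island genomes, methylomes, and
    capture-enriched read libraries so every step is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    dplyr,
    tibble,
    tidyr,
    ggplot2,
    generics,
    rlang,
    withr,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ape,
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
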