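Package: svkit
Title: Structural Variant Simulation, Consensus Calling and Population Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for population-scale structural variant (SV) analysis
    built around consensus calling from multiple SV callers. Simulates
    deletions, duplications, insertions, inversions and translocations into a
    reference genome with matched truth files; benchmarks callsets against
    truth (sensitivity and false discovery rate under breakpoint tolerance);
    merges multi-caller callsets by majority vote with paired-end support and
    repeat-region filters; genotypes copy-number variant (CNV) alleles from
    windowed read coverage using one-sided rank-sum tests and coverage-ratio
    thresholds; quantifies CNV transience within near-clonal clusters via
    copy-number trees and the relative-transience statistic; and computes the
    pairwise-distance and (partial) Kendall correlation statistics used to
    relate SV and SNP divergence to hybrid offspring viability.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    Biostrings,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
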