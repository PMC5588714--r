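Package: nrte
Title: Detection and Population Genomics of Non-Reference Transposable
    Element Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A split-read pipeline for detecting non-reference transposable
    element (TE) insertions in panels of resequenced inbred lines, together
    with the downstream population-genomic analyses such presence/absence
    markers support: genome-landscape window correlations, per-population
    frequency spectra, Hudson Fst with resampling confidence intervals, a
    Qst-Fst divergent-selection test, Gabriel-rule linkage-disequilibrium
    blocks, and a structure-corrected general-linear-model association scan.
    Includes a fully specified synthetic-data generator (reference genome,
    TE library, reads, phenotypes, expression) with a recorded truth set so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
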