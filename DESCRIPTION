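Package: epimsfs
Title: Methylation Site Frequency Spectrum Analysis and Epimutation
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-epigenetic analysis of cytosine methylation
    diversity. Builds the methylation site frequency spectrum (mSFS) from
    per-cytosine bisulfite calls across many accessions, fits the
    stationary distribution of a reversible-epimutation model with genic
    selection and drift by maximum likelihood (grid search over the
    population-scaled gain rate, the gain/loss bias and the selection
    coefficient), and simulates epimutation dynamics in mutation
    accumulation pedigrees and Wright-Fisher populations, including
    closed-form divergence curves and chromosome-scale diversity tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
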