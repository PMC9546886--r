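Package: pairedomics
Title: Repeated-Measures Multi-Omic Statistics for Paired Intervention Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for paired (pre/post intervention) multi-omic
    studies combining metabolic phenotyping and gut-microbiome profiling.
    Provides median fold change normalisation and spectral preprocessing,
    PLS-DA and OPLS-DA with jackknifed coefficient confidence intervals,
    a repeated-measures Monte-Carlo cross-validated PLS-DA engine with
    bootstrap variable inference and false-discovery-rate control, STOCSY
    statistical spectroscopy, Spearman and partial Spearman correlation
    networks, Euler set-overlap accounting, Bray-Curtis/PCoA/PERMANOVA
    beta-diversity inference, metagenomic gene-richness rarefaction, and a
    synthetic-data module that generates every input with recoverable ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
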