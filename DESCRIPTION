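Package: metscreen
Title: Deconvolution and Simulation of Pooled In Vivo Metastasis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and deconvolving pooled
    gain-of-function metastasis screens read out by barcode qPCR. Covers
    pool design under a detectability constraint (unique DNA barcodes,
    shuffle-then-chunk pooling with one GFP control per pool, simulation
    based pool-size power analysis), a stochastic generative model of
    barcode dynamics through the engraftment and lung-seeding bottlenecks,
    delta-delta-Ct quantification against a total-DNA reference probe and a
    pooled reference pellet, matched-pair lung-versus-mammary enrichment
    scores, and empirical-control hit calling with quadrant classification
    and ranked hit lists.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
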