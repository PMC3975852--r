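Package: mtgblup
Title: Single- and Multiple-Trait Genomic Prediction with Simulated Dairy
    Cattle Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time gene-drop simulation of a two-trait dairy
    cattle population with shared (pleiotropic) QTL, pedigree BLUP and
    GBLUP mixed-model machinery with REML variance-component estimation
    (average-information, EM and derivative-free direct search), pedigree
    (Henderson/Meuwissen-Luo) and genomic (VanRaden method 1) relationship
    matrices, and the evaluation statistics used to compare single-trait
    and multiple-trait genomic prediction models: validation reliability,
    regression of true on predicted breeding values before and after
    reliability rescaling, and the Hotelling-Williams test for dependent
    correlations. A scenario pipeline orchestrates replicated studies with
    missing-response masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
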