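Package: jointgblup
Title: Joint Multi-Population Genomic Prediction with Weighted GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic prediction across two
    genetically linked populations measured in different environments. Provides
    a forward-in-time simulator of diverged subpopulations with correlated SNP
    effects encoding genotype-by-environment interaction, SNP and individual
    quality control, the VanRaden method-1 genomic relationship matrix,
    single-trait and two-trait GBLUP models with de-regressed-proof reliability
    weighting fitted by average-information REML with an EM fallback, and
    evaluation of own-, cross-, and joint-reference prediction accuracy and
    unbiasedness by forward (cutoff-date) validation and replicated stratified
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
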