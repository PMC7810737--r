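Package: delirmetab
Title: Matched Case-Control Targeted Metabolomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for matched case-control targeted
    metabolomics studies of postoperative delirium: synthetic cohort
    simulation with a ground-truth ledger, quality-control based signal
    drift correction, internal-standard (NOMIS) normalization, k-nearest
    neighbour imputation, consensus paired univariate testing with
    Benjamini-Hochberg correction and split-resampling robustness, robust
    one-step biweight fold changes, OPLS-DA with cross-validated Q2,
    permutation and CV-ANOVA validation, VIP-panel SVM classification,
    and topology-aware hypergeometric pathway over-representation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    randomForest,
    e1071,
    igraph,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
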