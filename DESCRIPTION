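Package: icitools
Title: Single-Cell Analytics for Neoadjuvant Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the bespoke computations of
    neoadjuvant immune-checkpoint-inhibitor single-cell studies: discovery of
    recurrent malignant-cell meta-programs by consensus non-negative matrix
    factorization and gene co-occurrence networks, module scoring of single
    cells against expression-bin-matched controls, Pearson-residual analysis
    of cell-subset composition shifts, strict TCR clonotype calling with
    tumor-reactive T-cell extraction, aggregation and comparison of RNA
    velocity transition probabilities, differential-hub statistics on
    cell-type-specific gene networks, and a leave-one-study-out tree-ensemble
    classifier for testing signature-based response prediction. Ships a
    synthetic-data generator with planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    Matrix,
    methods,
    jsonlite,
    igraph,
    ranger,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
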