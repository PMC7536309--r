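Package: socovsel
Title: Multi-Block Biomarker Discovery with Sequential Orthogonalized
    Covariance Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering small discriminant biomarker panels from
    multi-platform ('multi-block') concentration tables with few samples and
    many correlated analytes. Implements covariance-based greedy variable
    selection (CovSel) with deflation, sequential orthogonalization of later
    blocks against variables already selected from earlier blocks, an additive
    multi-block regression on the selected variables, and linear discriminant
    analysis on the predicted response. Model block order and per-block
    complexity are chosen by repeated double cross-validation, with
    selection-frequency summaries, figures of merit with spread, and
    permutation tests of the observed classification accuracy. A synthetic
    data generator produces serum-panel-shaped datasets (three blocks,
    below-detection-limit censoring, planted discriminant variables) with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
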