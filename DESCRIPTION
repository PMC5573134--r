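Package: ralasso
Title: Robust Adaptive Lasso via Pearson-Residual Observation Weights
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse linear regression that is resistant to outliers in the
    response. Observations whose Pearson residuals indicate a mismatch
    between the empirical and an assumed model distribution are smoothly
    downweighted, and the weighted negative log-likelihood is minimised
    under an adaptive lasso penalty by cyclic coordinate descent over a
    regularisation path, with 10-fold cross-validation for the penalty
    level. Includes robust initial estimators (ridge for p >> n, Tukey
    bisquare M-estimation otherwise), baseline penalised fits (lasso,
    adaptive lasso, elastic net), a contamination simulation study engine
    with median prediction error and variable-selection metrics, CSV
    train/test case-study workflows, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
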