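Package: spcovr
Title: Sparse Principal Covariates Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simultaneous dimension reduction and prediction for
    high-dimensional data via sparse principal covariates regression: a small
    number of components, each a sparse linear combination of the predictor
    variables, is estimated so as to jointly reconstruct the predictor block
    and predict one or more outcomes.  Includes the exact (non-sparse)
    principal covariates regression solution, an alternating coordinate
    descent estimator with elastic-net penalised component weights,
    maximum-likelihood selection of the prediction/reconstruction weighting,
    a scree procedure for the number of components, stability selection with
    control of the expected number of falsely selected coefficients, a
    simulation-study generator with Tucker congruence and PRESS metrics, and
    preprocessing recipes for vaccine-response transcriptomics applications.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
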