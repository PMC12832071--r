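Package: panelsym
Title: Longitudinal Symptom Network Analysis for Two-Wave Panel Data
Version: 0.1.0
Authors@R: person("Panel", "Networks", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation and comparison of psychometric symptom networks from
    two-wave ordinal panel data. Provides regularized Gaussian graphical
    models (graphical LASSO with EBIC model selection), cross-lagged panel
    networks via penalized node-wise regression, a moment-based between- and
    within-person decomposition in the spirit of panel graphical vector
    autoregression, permutation-based network comparison tests, bootstrap
    edge-weight and centrality stability analysis (CS coefficients),
    chained-equation multiple imputation with predictive mean matching and
    Rubin's-rules pooling, Little's MCAR test, and a synthetic two-wave
    Likert panel generator with known network ground truth for parameter
    recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
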