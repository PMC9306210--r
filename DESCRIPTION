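Package: causalrd
Title: Risk-Difference Estimation for Unemployment-and-Health Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation machinery for studying the health effect of
    unemployment in cohort data: inverse-probability-weighted (standard,
    augmented and doubly-robust) risk-difference estimators, G-computation,
    logistic regression with profile-likelihood confidence intervals,
    percentile-bootstrap inference with bootstrap mean squared error and
    singular-replicate handling, derivation of employed/unemployed exposure
    status from labour-market histories under three measurement modes with a
    follow-up censoring policy, a 24-model confounder-sensitivity ledger, and
    a synthetic cohort generator with a Monte-Carlo evaluator of the true
    marginal risk difference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
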