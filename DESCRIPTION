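Package: gagfib
Title: Quantitative Modelling of Glycosaminoglycan-Mediated Acceleration of
    Amyloid Fibril Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of the accelerating effect of
    glycosaminoglycans (GAGs) on amyloid fibril formation kinetics. Converts
    aggregation kinetic traces into half-times and the log-acceleration
    statistic G, manages a curated literature entry table of protein, GAG and
    condition descriptors, reproduces single-parameter correlation analyses,
    fits and selects multivariate linear-quadratic models of G with full
    regression diagnostics (adjusted R-squared, variance inflation factors,
    Breusch-Pagan heteroscedasticity test), validates them by repeated
    train/test subsampling and leave-one-out jackknife, and generates
    synthetic datasets with the covariate structure of the curated database
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    lmtest,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
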