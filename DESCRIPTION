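Package: itrboost
Title: Individualized Treatment Rules and Predictive Biomarker Analysis
    with Gradient-Boosted Modified Losses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates individualized treatment rules (ITRs) for two-arm
    clinical trials by minimizing modified A-learning or inverse-propensity
    weight-learning losses with a gradient-boosted tree learner, for
    continuous, binary, and time-to-event endpoints. Provides predictive
    biomarker importance ranking, candidate-cutoff evaluation (Youden index,
    Cohen's kappa, Fisher exact, two-sample and log-rank tests), arm-by-
    biomarker-group performance tables with treatment-by-group interaction
    tests, biomarker-outcome association diagnostics (ROC, empirical CDF,
    penalized-spline outcome and treatment-contrast curves), and a
    synthetic-trial generator with known treatment-effect heterogeneity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
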