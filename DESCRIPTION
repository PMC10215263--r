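Package: sljump
Title: Standing Long Jump Length from Smartphone Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating standing long jump (SLJ) length
    from smartphone inertial measurement unit recordings. Reads Phyphox-style
    accelerometer/gyroscope exports, estimates and applies sensor calibration,
    expresses acceleration in the global frame with gravity removed, segments
    the jump preparation phase (onset, unloading, eccentric yielding, eccentric
    braking, concentric propulsion, take-off), extracts 61 anthropometric,
    ballistic, biomechanical and variational-mode-decomposition features,
    reduces them by Lasso, trains Bayesian-optimized regression models
    (linear, stepwise, SVM, tree ensembles, Gaussian process regression,
    neural networks) with 10-fold cross-validation, and evaluates agreement
    with Bland-Altman limits, Kendall's tau heteroscedasticity screening and
    permutation feature importance. A physics-based synthetic jump simulator
    with exact ground-truth annotations makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    xgboost,
    nnet,
    pracma,
    ggplot2,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
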