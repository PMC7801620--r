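Package: actisleep
Title: Embedded-Grade Sleep/Wake Classification from Raw Wrist Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for epoch-by-epoch sleep/wake scoring of raw triaxial
    wrist accelerometry with the lightCNNA dilated one-dimensional
    convolutional network, sized for microcontroller deployment (1361
    trainable parameters). Provides a synthetic actigraphy cohort
    generator, CSV ingest and clock alignment against reference
    hypnograms, unfiltered decimation and min-max normalization,
    90-second context windowing, pure-R training with the Adam
    optimizer, decision-threshold calibration by the
    specificity-sensitivity balance point, leave-one-subject-out
    validation with Cohen's kappa and night-level sleep metrics (total
    sleep time, wake after sleep onset, sleep efficiency), Bland-Altman
    agreement, ROC and precision-recall analysis, and six feature-based
    reference classifiers evaluated under the identical folds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
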