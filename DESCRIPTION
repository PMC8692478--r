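Package: glucotcn
Title: Multi-Step Blood Glucose Forecasting with Temporal Convolutional
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-patient multi-step forecasting of continuous glucose
    monitor (CGM) readings for type-1 diabetes. Implements a
    four-component temporal-convolutional encoder-decoder with a
    learnable parametric fusion layer and an event-weighted Huber loss,
    together with CGM preprocessing (gap interpolation, segment
    splitting, calibration rejection, eligibility and quality filters,
    min-max scaling, multi-view windowing), reference predictors (naive
    persistence, kernel ridge regression, Gaussian-process regression,
    ARX), a clinical evaluation suite (RMSE/MAE/MAPE/NRMSE, per-category
    sensitivity and false-positive rates, Clarke and Parkes error
    grids), and a seedable virtual-patient simulator so the whole
    pipeline runs end-to-end without any real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    deSolve,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
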