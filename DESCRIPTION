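Package: wtlcc
Title: Windowed Time-Lagged Cross-Correlation Analysis of Brain-Heart
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives cerebral hemodynamic (ICP, CPP, PRx) and autonomic
    (baroreflex sensitivity, LF/HF heart-rate-variability ratio) indices from
    high-resolution arterial and intracranial pressure waveforms, builds
    windowed time-lagged cross-correlation (WTLCC) matrices between index
    pairs, and classifies patient outcome from those matrices with a compact
    convolutional neural network using patient-level mean-score aggregation.
    Includes a gradient-boosted-trees comparison on averaged indices adjusted
    for CRASH clinical covariates, cohort comparison statistics, and a coupled
    brain-heart signal simulator with known ground-truth physiology for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    yaml,
    pracma,
    xgboost,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
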