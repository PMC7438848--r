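Package: epidisc
Title: Epileptiform Discharge Detection from Scalp EEG via Adaptive
    Fractal and Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: First-principles separation of epileptiform-discharge EEG
    epochs from normal ones. Implements adaptive fractal analysis (AFA)
    for short-scale Hurst exponent estimation on nonstationary signals,
    Signal Range and band-energy features, 19x19 channel-difference
    feature networks summarised by the square of their first singular
    value, random-forest classification with ROC/AUC evaluation, and a
    singular-vector projection procedure that localises discharges on
    the scalp. A synthetic 19-channel EEG generator (fractional Gaussian
    noise background, alpha rhythm, planted discharge templates of the
    seven standard types) provides ground truth for every stage, and a
    minimal EDF reader/writer handles real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    randomForest,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
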