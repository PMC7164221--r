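Package: gaitintent
Title: Prediction of Gait Intention from Pre-Movement EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully predictive gait-intention decoding pipeline for
    eight-channel sensorimotor EEG. Generates synthetic gait sessions with
    controllable pre-movement event-related desynchronization, cleans
    recordings (resampling, FIR high-pass, 60 Hz notch, bad-channel
    rejection, artifact-subspace burst repair, common-average reference),
    segments balanced rest/start and walk/stop epochs around gait events,
    extracts Hjorth activity/mobility/complexity features from db4 wavelet
    alpha and beta sub-band reconstructions over sliding sub-windows, ranks
    features by the absolute standardized Wilcoxon rank-sum statistic with a
    redundancy penalty, and evaluates cost-sensitive RBF-kernel support
    vector machines by stratified ten-fold cross-validation with
    cross-window statistical comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
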