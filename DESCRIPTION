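Package: eegactivity
Title: EEG-Based Human Activity Recognition with Spectral Features and
    Local Surrogate Explanations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for recognizing everyday human
    activities (resting, reading, walking, working) from multichannel EEG.
    Includes a synthetic EEG simulator with known activity-dependent spectral
    structure and controlled artifacts; preprocessing (60 Hz notch, FastICA
    artifact removal against reference channels, SNR-based epoch rejection,
    0.5-44 Hz band-pass); Welch-periodogram spectral features (relative band
    powers, pairwise-derived brain symmetry index, delta/alpha, delta/theta
    and slow/fast-wave power ratios); univariate feature selection; ensemble
    tree classifiers (random forest, gradient boosting, extreme gradient
    boosting) with stratified splits and cross-validated tuning; evaluation
    (confusion matrix, precision/recall/F1/accuracy, one-vs-rest ROC/AUC);
    and a from-scratch tabular local-surrogate (LIME-style) explainer that
    reports signed per-feature contributions for single predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
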