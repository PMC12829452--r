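Package: eegcnn
Title: Resting-State EEG Classification with Time-Frequency CNNs and
    Subject-Level Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-group classification of resting-state
    EEG recordings: seeded synthetic EEG cohort and covariate simulation,
    artifact-aware preprocessing (FIR filtering, FastICA-based ocular
    component removal, common-average referencing, overlapping epoching with
    peak-to-peak rejection), Morlet wavelet log-power time-frequency
    features, an epoch-level two-block 2D convolutional network and a
    Welch band-power RBF support-vector-machine baseline, leave-one-subject-out
    cross-validation with leakage-safe per-fold standardization and
    epoch-to-subject probability aggregation, late-fusion stacking of the
    EEG score with clinical and demographic covariates, and classification
    reporting (confusion matrices, per-class precision/recall/F1, ROC AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    ica,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
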