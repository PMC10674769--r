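Package: armfatigue
Title: Upper-Limb Muscle-Fatigue Estimation from Wearable Sensor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for estimating biceps-brachii muscle fatigue during
    repetitive lifting from wearable, non-invasive sensors: an optical-fiber
    elbow-angle sensor, surface EMG, and two inertial measurement units (wrist
    and neck). Raw multi-rate streams are calibrated and filtered, biceps-curl
    repetition cycles are segmented from the elbow-angle signal, 63 per-cycle
    features (amplitude, duration and spectral families, including the
    wavelet-based instantaneous mean frequency) are extracted and normalized to
    each subject's first repetition, and three ordinal fatigue states derived
    from Borg CR10 ratings are classified with subject-wise cross-validated
    tree ensembles. Includes a synthetic-cohort simulator reproducing the
    fatigue physiology the analysis assumes (rising EMG amplitude, falling EMG
    spectral frequency, slowing cycles, shrinking range of motion, growing neck
    compensation), split-importance feature ranking, and sensor-ablation
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    ranger,
    rpart,
    signal,
    stats,
    tibble,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
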