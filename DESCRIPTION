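Package: spocflow
Title: Single-Trial Motor Performance Prediction from Pre-Trial EEG
    Bandpower via Supervised Spatial Filtering (SPoC)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts single-trial motor performance from the bandpower of
    oscillatory EEG activity preceding movement. Implements force-trajectory
    performance metrics (reaction time, duration, cursor path length,
    integrated squared jerk, normalized jerk), epoch extraction and artifact
    rejection, the Source Power Comodulation algorithm (SPoC-lambda) solved
    as a generalized eigenvalue problem, chronological cross-validated
    bandpower prediction, a robustness battery (fold homogeneity, z-AUC
    separability, label-noise stress testing) and a frequency-band grid
    scan with a channel-wise regression baseline. Includes a forward-model
    synthetic data generator with planted target-comodulating narrowband
    sources for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
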