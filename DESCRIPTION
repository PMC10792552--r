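Package: anesmap
Title: Mapping Anesthesia Depth States from EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated signal-processing pipeline for mapping brain states
    during isoflurane general anesthesia from single-channel EEG (plus
    optional EMG). Detects iso-electric suppressions (IES) and band
    suppressions with adaptive RMS-based thresholds, computes sliding-window
    suppression and band-power ratios, separates the power spectrum into an
    aperiodic a/(c+f^p) trend and Gaussian-parameterized oscillatory rhythms
    using irregular-resampling auto-spectral analysis (IRASA) on sliding
    windows, tracks theta/delta rhythm center frequencies over time, detects
    the post-anesthesia gamma rebound, assembles the ordered chain of
    time-frequency events, labels anesthesia-depth states, and predicts IES
    sensitivity with a group-aware, stratified cross-validated logistic
    regression. A seeded synthetic EEG/EMG generator with known ground truth
    supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    pROC,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
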