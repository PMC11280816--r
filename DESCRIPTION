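Package: cobls
Title: Convolutionally Optimised Broad Learning for Noise-Robust ECG
    Heartbeat Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anti-noise arrhythmia recognition from single-lead ECG beats.
    Replaces the random feature mapping of the broad learning system (BLS)
    with a two-layer cascaded convolutional feature extractor whose kernels
    are learned by independent component analysis (FastICA) and principal
    component analysis, followed by Heaviside binarisation, power-of-two
    decimal coding and overlapping block histograms; the classifier head is
    a closed-form ridge-regression BLS with random enhancement nodes.
    Includes a synthetic ECG beat generator with calibrated SNR-controlled
    Gaussian noise injection, a minimal WFDB record/annotation reader with
    AAMI class mapping, the standard confusion-matrix metric suite, and
    stratified 10-fold cross-validation with pooled-fold reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
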