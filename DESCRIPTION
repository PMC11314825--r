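Package: rpaf
Title: Recurrence-Plot Analysis of Single-Lead ECG for Atrial Fibrillation Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for screening single-lead electrocardiograms for imminent
    atrial fibrillation. Implements min-max normalisation and adaptive wavelet
    soft-threshold denoising (Daubechies-5 filter bank), time-delay phase-space
    embedding, thresholded recurrence-plot construction, the standard recurrence
    quantification statistics (recurrence rate, determinism, entropy, trapping
    time, laminarity, mean and maximal diagonal line), and a small residual
    convolutional network that classifies recurrence-plot images (or raw
    segments) into pre-fibrillation and non-fibrillation classes. A synthetic
    ECG generator with controllable rhythm irregularity and realistic noise
    (baseline drift, powerline interference, muscle artifact) makes the whole
    pipeline testable without clinical data. Includes WFDB and CSV readers,
    resampling, segmentation, record-disjoint dataset splitting, evaluation
    metrics (accuracy, precision, recall, F1, ROC/AUC), and an end-to-end
    pipeline driver with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
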