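Package: ppg2bp
Title: Cuffless Blood Pressure Estimation from Photoplethysmogram Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates systolic and diastolic arterial blood pressure from
    photoplethysmogram (PPG) waveforms without a cuff. Provides waveform record
    input/output (delimited text and WFDB-style records), a synthetic PPG+ABP
    generator with known per-beat ground truth, preprocessing (median-filter
    baseline correction, zero-phase low-pass filtering, fixed-window
    segmentation, beat-wise SBP/DBP reference extraction from the arterial
    pressure channel), extraction of 17 time-domain and 7 chaotic features
    (entropies and fractal dimensions) per segment, seven regression models
    (linear, robust linear, Gaussian process regression with rational
    quadratic, squared exponential and Matern 5/2 kernels, and epsilon support
    vector regression with linear and Gaussian kernels), and cross-validated
    evaluation with RMSE, MSE, MAE, MAPE, R-squared, Pearson correlation,
    Bland-Altman agreement analysis and British Hypertension Society blood
    pressure grading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    kernlab,
    optparse
Config/testthat/edition: 3
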