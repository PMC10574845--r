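Package: ppgbp
Title: Cuff-Less Blood Pressure Estimation from Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for estimating systolic and diastolic blood
    pressure from single-site photoplethysmography (PPG) waveforms paired
    with invasive arterial blood pressure (ABP) references. Provides a
    synthetic 125 Hz PPG/ABP waveform generator with analytic ground truth,
    the signal-conditioning chain (alignment, band-pass denoising, Z-score
    standardization, baseline correction, foot-to-foot pulse segmentation,
    quality and shape-similarity gating, per-pulse SBP/DBP labeling and
    range filtering), a maximal overlap discrete wavelet transform (MODWT)
    with additive multiresolution analysis for pulse enhancement, a
    versioned morphology feature registry over raw and enhanced pulses,
    mRMR and RReliefF feature selection, gradient-boosted regression tuned
    by Gaussian-process Bayesian optimization plus a Nadam-trained neural
    network baseline, and clinical validation statistics (AAMI, BHS
    grading, ESH/ESC seven-class hypertension classification,
    Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    signal,
    stats,
    utils,
    xgboost
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
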