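Package: voltachemo
Title: Chemometric Resolution of Overlapping Differential-Pulse Voltammograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate calibration pipeline for simultaneous quantification
    of co-oxidizing analytes (levodopa, carbidopa, entacapone) from overlapping
    differential-pulse voltammograms. Provides a synthetic voltammogram
    generator with drift, potential jitter and noise; adaptive iteratively
    reweighted penalized least squares (airPLS) baseline correction; interval
    correlation optimised shifting (icoshift) alignment; Savitzky-Golay
    derivative filtering and column scaling; Brereton multilevel multifactor
    calibration designs; NIPALS partial least squares regression with
    cross-validated latent-variable selection; model validation diagnostics
    (RMSECV/RMSEP/REP, CV-ANOVA, permutation testing, leverage, Hotelling T2,
    standardized residuals); and analytical eco-scale greenness scoring with
    two-method t/F comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
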