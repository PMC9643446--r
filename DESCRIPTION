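Package: resteeg
Title: Resting-State EEG Biomarker Pipeline with Synthetic Cohorts and
    Nested Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a comprehensive battery of resting-state EEG biomarkers
    from source-patch time series (spectral band power, hemispheric asymmetry,
    theta/beta ratio, peak alpha frequency, aperiodic 1/f exponent, detrended
    fluctuation analysis exponents, functional excitation/inhibition ratio,
    and five phase- and amplitude-based functional connectivity measures
    collapsed to region-level connections), screens and detrends linear age
    effects, runs univariate group statistics (permutation tests on means,
    Levene's test on variances, FDR control within feature families), and
    evaluates multivariate prediction with mRMR feature selection inside a
    repeated, stratified two-layer cross-validation framework. Includes a
    synthetic-cohort generator with controllable spectral slopes, oscillatory
    peaks, long-range temporal correlations and pairwise coupling, so that
    every estimator can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
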