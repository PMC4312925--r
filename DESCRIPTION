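Package: mvpaproj
Title: Confound-Aware Multivoxel Pattern Classification with
    Projection-Based Corrections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multivoxel pattern analysis
    (MVPA) of event-related fMRI with explicit control of two classifier
    confounds: between-condition differences in mean signal amplitude and
    signal modulation by response time. Provides a synthetic data generator
    for voxel-by-trial response-amplitude matrices with known injected
    pattern, mean-amplitude and response-time-coupled effects (optionally via
    BOLD-like timeseries and single-trial GLM estimation), two orthogonal
    projection corrections (mean-signal removal and response-time
    residualization), a per-subject linear support-vector-machine decoding
    scheme with class down-sampling, run-wise cross-validated regularization
    tuning and held-out testing, group-level one-sample t statistics against
    chance with label-permutation significance testing, and named simulation
    scenarios that recover which corrections abolish which kind of signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
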