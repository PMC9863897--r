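Package: thermomyo
Title: Contactless Estimation of Muscle Activity and Fatigue from Thermal Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates surface-EMG muscular activity (average rectified value,
    ARV) and fatigue (median frequency, MDF) metrics from infrared-thermal-imaging
    skin-temperature features. Implements EMG preprocessing (zero-lag Butterworth
    high-pass, Welch spectra), nine thermal time-series features including sample
    entropy and spatial gradients, univariate F-test feature selection, nested
    leave-one-subject-out cross-validated regression across five model families
    (linear, linear/Gaussian-kernel support vector regression, bagged trees,
    Gaussian processes), and a Bland-Altman style agreement battery. Ships a
    synthetic cohort generator with known EMG-thermal coupling for recovery and
    null-calibration studies.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
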