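Package: optomyo
Title: Optical Myography: Finger-Movement Intent from Forearm Marker Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps time series of 6-DOF fiducial-marker poses tracked on the
    forearm surface to intended finger-movement activations. Provides a
    synthetic forearm-deformation generator emulating a square-sinusoidal
    visual-stimulus protocol, Butterworth bandpass preprocessing with
    last-known-position imputation of undetected markers, closed-form Ridge
    Regression and Random-Fourier-Feature Ridge Regression, five
    cross-validation scheme designs with hyperparameter grid search and NRMSE
    evaluation, cross-subject aggregation with Student t-tests, and
    robustness procedures (contrast/brightness and Gaussian-blur image
    perturbation operators, proximal-marker trimming).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
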