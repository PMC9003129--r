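Package: enkfecg
Title: Fetal ECG Extraction from Single-Channel Abdominal Recordings with
    the Ensemble Kalman Filter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Separates the fetal electrocardiogram from a single-channel
    maternal abdominal recording. Implements the polar-coordinate dynamic
    ECG model with Gaussian PQRST waves, Kalman, extended Kalman and
    ensemble Kalman filters over that model, a two-pass
    maternal-cancellation and fetal-denoising pipeline, Pan-Tompkins QRS
    detection, stationary-wavelet denoising, motion-artifact synthesis and
    injection, an annotated abdominal-mixture simulator, and
    beat-detection scoring (sensitivity, positive predictive value, F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
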