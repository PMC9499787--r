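Package: pulsekit
Title: Arterial Pulse Waveform Denoising, Fiducial Detection, and Mai Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing arterial pressure pulse recordings: dyadic
    wavelet denoising with automatic decomposition-level selection, ensemble
    empirical mode decomposition with Hilbert instantaneous-frequency band
    filtering, differential-threshold detection of the five pulse fiducial
    points (onset, main wave, tidal wave, dicrotic notch, dicrotic wave),
    wavelet-energy feature vectors, onset-anchored segmentation with
    cross-interception augmentation, and a fixed-architecture one-dimensional
    convolutional network for classifying ten traditional pulse (Mai) types.
    Includes a synthetic pulse generator with ground-truth fiducials so the
    full pipeline is testable without access to sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    signal,
    utils,
    zoo
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
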