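Package: willdecode
Title: Decoding Self-Initiated Covert Spatial Attention from EEG Alpha Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decoding the direction of
    self-initiated ("willed") covert visuospatial attention from posterior
    EEG alpha-band (9-11 Hz) power. Provides a synthetic multichannel EEG
    session generator with known ground truth (lateralized occipital alpha,
    central mu rhythm, flicker-driven components, 1/f background, blink
    artifacts), preprocessing (re-referencing, zero-phase band-pass
    filtering, downsampling, epoching, moving-window peak-to-peak artifact
    and eye-movement rejection), alpha-band time-frequency extraction with
    an adaptive three-cycle Hann taper, spherical-spline surface Laplacian
    current source density, irregular-resampling spectral separation of
    fractal and oscillatory components, trial-equalized fold-averaged
    support-vector-machine decoding at each timepoint, cluster-based
    Monte-Carlo significance testing, lateralization statistics, and
    figure-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
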