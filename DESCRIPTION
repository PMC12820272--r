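Package: ripplefloor
Title: Noise-Floor Benchmarking of Sharp-Wave Ripple Detectors on 1/f
    Background Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation-based estimation of the false-positive rate of
    sharp-wave ripple detectors in electrophysiological recordings.
    Generates colored 1/f noise with constant or time-varying spectral
    exponents, builds exponent-matched surrogate recordings, parameterizes
    the aperiodic (1/f) component of power spectra, implements five
    published ripple detection algorithms plus an interictal-discharge
    detector behind a shared envelope-thresholding engine, and provides
    the analytics to characterize each detector's noise floor:
    density-versus-exponent sweeps, density profiles binned by spectral
    exponent, percent-of-detections-within-noise-floor estimates, and
    trial-locked density statistics (repeated-measures ANOVA, Spearman and
    partial correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
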