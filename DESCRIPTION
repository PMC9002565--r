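Package: besct
Title: Bayesian-Embedded Spline-Kerneled Chirplet Transform and
    Spectrum-Aware Motion Magnification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Time-frequency analysis of nonstationary, nonlinearly
    frequency-modulated signals by a spline-kerneled chirplet transform
    (SCT) embedded in an empirical-Bayes state-space model: per-frequency
    complex Kalman filtering and fixed-interval smoothing of spectral
    increments under a random-walk continuity prior, with observation and
    innovation variances estimated by an EM algorithm under gamma priors.
    The denoised spectrogram drives a spectrum-aware video motion
    magnification pipeline: an earth mover's distance global-motion metric,
    amplitude-thresholded passband scheduling, and phase-based Eulerian
    magnification through a complex steerable pyramid, with a synthetic
    ground-truth video generator and PSNR/MAE evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils, splines, png, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
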