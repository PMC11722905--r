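Package: narxgrip
Title: Grip-Force Decoding from Surface Electromyography with NARX Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for decoding continuous, dynamic grip force from
    multi-channel surface electromyography (sEMG). Provides a seeded
    simulator of cyclic grip protocols (trapezoidal activation, band-limited
    EMG carrier, baseline drift, powerline interference, motion artifacts),
    a preprocessing chain (robust outlier interpolation, zero-phase
    Butterworth band-pass and notch filtering, wavelet-threshold denoising,
    polynomial baseline-drift removal, envelope downsampling), a nonlinear
    autoregressive network with exogenous inputs (NARX) fitted by nonlinear
    conjugate gradient, Levenberg-Marquardt, or Bayesian-regularized
    stochastic gradient descent, and an evaluation harness with temporal
    splits, hidden-size by delay parameter sweeps, and phase-resolved error
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
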