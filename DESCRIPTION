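Package: photokin
Title: Global and Target Analysis of Time-Resolved Spectra with
    Photoselection and Multi-Pulse Finite-Bleach Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the kinetic analysis of time-resolved (transient
    absorption) spectroscopy. Connectivity schemes of first-order reactions
    are solved to concentration profiles (matrix exponential with a stiff
    numerical fallback) and fitted globally to delay-by-wavelength data
    matrices by variable projection: shared rate constants, instrument
    response function and chirp parameters are optimised nonlinearly while
    per-channel spectra and offsets are eliminated by linear least squares.
    Includes singular value decomposition utilities for rank estimation and
    trace fitting, Gaussian IRF convolution with polynomial chirp modelling
    and estimation, gradient and pattern-search optimisers, a synthetic
    benchmark generator, and the photoselection theory for intense polarised
    pulses: orientational photolysis fractions, ensemble averages, optical
    anisotropy, Gaussian beam profiles, pump/probe beam-ratio and depth
    corrections, and multi-pulse (pump-dump-probe) finite-bleach populations
    with ground-state recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
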