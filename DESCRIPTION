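Package: phirf
Title: Phase-Dependent Impulse Response Functions for Rhythmic Movement Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of phase-dependent impulse response functions (phiIRFs)
    of rhythmic limit-cycle systems, such as human treadmill walking, from
    continuous sensory and mechanical perturbations. Implements gait-phase
    estimation from cycle events with a causal second-order filter, resampling
    of signals from time to phase, Welch power- and double-frequency
    cross-spectral densities yielding harmonic transfer function (HTF) modes,
    conversion of HTFs to transient, phase and full time-domain phiIRFs with a
    phase-resetting correction, a linearized response predictor, group-level
    normal-theory confidence intervals and sign-flip permutation tests with
    tmax family-wise error control, generators for filtered-white-noise
    perturbation signals and EMG/kinematic preprocessing chains, and a
    configurable limit-cycle "walker" surrogate whose true phiIRF is computable
    by brute-force impulse experiments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
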