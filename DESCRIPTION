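Package: phasecoupler
Title: Bayesian Inference of Phase-Coupling Functions from Rhythmic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates coupled phase-oscillator models - natural frequencies,
    n:m cross-frequency coupling functions and noise strengths - from rhythmic
    time-series data such as band-filtered EEG, speech envelopes or circuit
    voltages. Raw signals are converted to corrected, unwrapped phases via the
    analytic signal and a protophase-to-phase transformation; coupling
    functions are expanded in truncated Fourier series and fitted by conjugate
    Bayesian linear regression with a Gaussian inverse-gamma prior; the
    Fourier order of each directed coupling is selected by maximising the
    logarithmic model evidence. Includes a stochastic (Euler-Maruyama) phase
    model simulator, a two-oscillator van der Pol circuit ground-truth
    generator with adjoint-method theoretical coupling functions, coupling
    ablation, phase-difference histograms and time-shift surrogate testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
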