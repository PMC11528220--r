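Package: lfpdyn
Title: Low-Power Neural Decoding with LFP-Driven Latent Dynamics Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building intracortical brain-computer interface (iBCI)
    decoding pipelines that run on local field potential (LFP) band power
    instead of high-bandwidth spiking. Provides a synthetic session
    generator with latent-dynamics-driven Poisson spiking and coupled LFP
    power, signal preprocessing (short-time Fourier band power, channel
    quality control, causal normalization, quantization, spike cleaning),
    behavioral event detection, a sequential variational autoencoder with
    Poisson emissions that reconstructs firing rates from LFP power,
    regularized Wiener-filter kinematic decoding with cross-validated
    metrics, and closed-form analog front-end power budgeting (amplifier
    noise-efficiency-factor and ADC Schreier figure-of-merit models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
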