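Package: lnspike
Title: Linear-Nonlinear Rate-Model Reduction of Spiking Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Izhikevich and augmented multi-adaptive-threshold (AMAT)
    spiking neuron model classes driven by Poisson spike-train input, injected
    current and background noise, and reduces them to linear-nonlinear (LN)
    firing-rate models. Provides stimulus generators (sinusoidal and piecewise
    constant inhomogeneous Poisson trains, synthetic retinal-ganglion-cell-like
    trains), response characterization (fixed-kernel rate estimation, harmonic
    decomposition with a significance criterion, activation functions, linearity
    scores), estimation and constrained fitting of bandpass transfer functions,
    rate prediction by convolution or by an equivalent ODE system, fit-quality
    scoring, model generalization, and grouping of model variants by clustering
    fitted filter parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
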