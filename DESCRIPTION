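Package: gammaEI
Title: Excitatory-Inhibitory Resonance Model of Cortical Gamma with an
    LFP and Spiking Analysis Pipeline
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a lumped Wilson-Cowan-type excitatory-inhibitory
    (E-I) network in which lateral recurrent inputs are folded into
    effective synaptic weights, and analyses its gamma-band resonance:
    fixed points, nullclines, Hopf bifurcation scans, input-plane maps of
    oscillation power and frequency, and weight-perturbation experiments
    that model stimulus discontinuities as reductions of recurrent
    excitation.  Alongside the model, the package implements an
    electrophysiology analysis pipeline for local field potentials and
    spiking units: single-taper (Slepian) time-frequency difference
    spectra in decibel, stimulus-versus-baseline change in power,
    gamma-band selection and band power, per-site normalization,
    firing-rate tuning, discontinuity-regression slopes, and paired
    signed-rank comparisons of slope magnitudes.  Seeded
    synthetic-session generators (1/f-type LFP noise with an injected
    narrowband gamma component, inhomogeneous-Poisson spiking,
    2D-Gaussian receptive-field grids) provide ground-truth data for
    end-to-end recovery studies, including a model-driven mode that
    turns E-I simulations into LFP-like trials.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
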