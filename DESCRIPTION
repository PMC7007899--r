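Package: posturolab
Title: Posturography Stimulus Design, Closed-Loop Sway Simulation and
    Learning-Trial Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for support-surface tilt posturography. Generates
    pseudo-random ternary tilt sequences and short rhythmic two-sine
    learning stimuli, simulates standing balance as a delayed-feedback
    inverted pendulum with proprioceptive/graviceptive weighting and
    torque noise, calibrates centre-of-mass sway from centre-of-pressure
    regression, estimates cycle-averaged frequency response functions and
    coherence, computes per-trial learning metrics (spectral partitions,
    drift, feedback score, gain and phase at stimulus frequencies),
    attaches cycle-resampling bootstrap confidence bounds, and fits a
    hierarchical Bayesian random-slope trend model across learning trials.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    rjags,
    coda,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
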