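Package: turbfmri
Title: Whole-Brain Turbulent Dynamics for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free and model-based measures of whole-brain turbulent
    dynamics on parcellated resting-state BOLD time series. Implements the
    local Kuramoto order parameter across spatial scales, amplitude
    turbulence, node-level metastability, information cascade flow and
    information transfer; a Stuart-Landau (Hopf) whole-brain oscillator
    network with exponential-distance-rule coupling, global-coupling fitting
    against functional-connectivity-versus-distance curves, and an in-silico
    perturbation protocol yielding susceptibility and information encoding
    capability; permutation rank-sum group inference with FDR control and
    effect sizes, node-level analysis with resting-state-network attribution,
    and a balanced radial-kernel SVM classifier of treatment response with
    permutation significance. A synthetic-cohort generator (geometry,
    connectome, coupled-oscillator BOLD with group-graded coupling, outcome
    scores) makes the full analysis runnable and testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'connectome.R'
    'turbulence.R'
    'hopf.R'
    'cohort.R'
    'perturbation.R'
    'inference.R'
    'classifier.R'
    'io.R'
    'pipeline.R'
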