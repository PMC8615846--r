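Package: pitconnect
Title: Effective Connectivity and Behavior in an Avoidance Pavlovian-to-Instrumental Transfer Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis workflow for an avoidance-based
    Pavlovian-to-instrumental transfer (PIT) fMRI experiment. Generates task
    schedules, behavioral agents and ground-truth BOLD time series from an
    extended unified structural equation model (euSEM); runs the behavioral
    analysis (attack-count learning tests, response-rate normalization,
    three-way repeated-measures ANOVA with Greenhouse-Geisser correction and
    generalized eta squared, Bonferroni pairwise probes); extracts sphere-mask
    ROI time series; estimates person-specific hemodynamic response functions
    by smoothed finite impulse response; and infers group- and
    individual-level effective-connectivity maps by iterative group model
    estimation (GIMME) with modification-index search and pruning.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
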