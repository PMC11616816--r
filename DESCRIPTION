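Package: gatingERP
Title: Decomposition of Working-Memory Gating Subprocesses from
    Reference-Back Behaviour and Event-Related Potentials
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for the reference-back
    working-memory paradigm. Generates balanced trial sequences with the
    standard block structure, simulates per-subject reaction times and
    multichannel ERP epochs, and decomposes behaviour and difference
    potentials into the four gating subprocesses (updating, substitution,
    gate opening, gate closing). Inference includes tmax sign-flip
    permutation tests with familywise error control, split-plot
    (mixed) ANOVA with Greenhouse-Geisser correction and partial eta
    squared, JZS Bayes-factor t tests, BIC-based inclusion Bayes factors,
    Mann-Whitney tests with rank-biserial correlation, and a simplified
    sLORETA standardized minimum-norm source inverse on synthetic lead
    fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Electrophysiology, TimeCourse, StatisticalMethod, Bayesian
RoxygenNote: 7.3.3
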