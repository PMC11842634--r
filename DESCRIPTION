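Package: SSVEPcoupling
Title: Response Coupling of Error-Related Potentials with Phase-Locked SSVEPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of response-coupled EEG experiments in
    which error-related potentials (ErrPs) are elicited concurrently with a
    phase-locked steady-state visual evoked potential (SSVEP). Provides a
    seeded generator for coupled-EEG cohorts; Butterworth band-pass filtering,
    electrode-subset selection and threshold artifact rejection over a 9-cell
    spatio-spectral configuration grid; Hilbert analytic signals,
    phase-locking values, stimulus templates, cross-correlation delay
    analysis and stimulus-response phase-lag estimation; an unsupervised
    SSVEP fidelity score for data-quality screening; and an xDAWN +
    Riemannian tangent-space + elastic-net single-trial ErrP detector with
    per-user cross-validation and zero-shot generalization protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    methods,
    stats,
    utils,
    tools,
    signal,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
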