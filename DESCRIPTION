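Package: rtnf
Title: Simulation and Analysis of Closed-Loop fMRI Network Neurofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse real-time fMRI neurofeedback
    experiments that target large-scale brain networks such as the default
    mode network (DMN) and central executive network (CEN). Provides a
    synthetic BOLD generator with planted network structure, an ICA-based
    personalized network localizer, an incremental general linear model
    feedback engine with an adaptive visual staircase, offline
    seed-connectivity analysis (framewise displacement, aCompCor, band-pass
    denoising, Fisher-z maps, small-volume FDR), and the inferential layer
    (correlation and t tests, intraclass correlation, Baron-Kenny mediation
    with the Sobel test). Every stage runs on synthetic data so the full
    pipeline is testable without any acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    tools,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
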