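Package: senliver
Title: Dynamics of Senescence-Driven Acute Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a six-variable mass-action ordinary
    differential equation model of acute senescence-driven liver injury, in
    which an initial bolus of senescent hepatocytes recruits pro-inflammatory
    (M1) and pro-regenerative (M2) macrophages, activates the endothelium and
    myofibroblasts, and deposits extracellular matrix. Provides adaptive
    Runge-Kutta trajectory simulation with outcome classification (resolution
    versus uncontrolled inflammation), steady-state and linear-stability
    analysis, bisection for the critical initial senescence threshold,
    clearance-time and threshold parameter sweeps, a seeded generator of
    synthetic per-animal fold-change datasets emulating qPCR and histology
    readouts, and a qualitative model-data validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
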