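Package: anophys
Title: Simulation and Analysis of Ca2+-Activated Scramblase Currents and
    Phospholipid Scrambling Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of whole-cell voltage-clamp
    recordings from Ca2+-activated TMEM16 scramblase/channel proteins and of
    annexin-V phospholipid-scrambling assays. Includes a multi-ligand
    (EGTA/HEDTA) buffered free-Ca2+ equilibrium solver for pipette-solution
    design, a mechanistic synthetic-data generator (Ca2+-shifted Boltzmann
    gating, Goldman-Hodgkin-Katz open-channel permeation, single-exponential
    relaxation, leak, capacitative transients, cell-to-cell variability),
    threshold-potential detection against a noise criterion, relaxation and
    tail-current reversal-potential fitting, Hill-type Ca2+-dependence fits,
    scrambling onset-latency quantification, and the accompanying
    statistical summaries and group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
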