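Package: adaswitch
Title: Stochastic Activation of the E. coli Adaptive Response in Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative simulator and analysis pipeline for cell-to-cell
    heterogeneity in the Escherichia coli adaptive response to DNA
    alkylation damage. Simulates the stochastic Ada master switch (basal
    birth-death expression, single-molecule methylation trigger, positive
    feedback amplification), alkylation lesion dynamics with saturable
    basal repair, DNA mismatch (MutL focus) formation, mutation fixation,
    and cell death, together with the observation models of mother-machine
    fluorescence microscopy, single-molecule protein counting, and flow
    cytometry. Analysis stages cover baseline correction and
    activation-delay calling from fluorescence traces, dual-reporter delay
    regression and steady-state cross-correlation with null controls,
    Poisson fits of censored molecule-count snapshots, mismatch-rate and
    survival curves, and FACS gating with per-subpopulation mutant
    frequencies and plasticity shares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
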