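Package: pharmpanel
Title: Drug-Sensitivity Panel Analysis: IC50 Fitting, Median-Effect
    Synergy, Potency Clustering and Expression Screens
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing compound screens across cancer cell-line
    panels: normalisation of fluorescence plate data against untreated
    controls, four-parameter logistic IC50 estimation with censoring,
    Chou-Talalay median-effect analysis and combination-index scoring of
    constant-ratio drug pairs, Ward clustering of compound potency
    fingerprints, a gene-expression/potency Pearson correlation screen
    with signal filtering and multiple-testing context, GO Biological
    Process term-frequency summaries, and pharmacokinetic exposure
    contextualisation. Includes synthetic-data generators with known
    ground truth so the entire pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
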