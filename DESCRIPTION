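Package: corereg
Title: Constraint-Based Metabolic Modeling and Core Regulatory Set
    Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constraint-based analysis of genome-scale metabolic
    models: flux balance analysis (FBA) and flux variability analysis (FVA)
    on a built-in bounded-variable simplex solver, SBML Level 3 (FBC) and
    tabular model input/output, elemental and charge balance checking with
    proton/water rebalancing, detection and curation of thermodynamically
    infeasible cycles via the null space of the stoichiometric matrix,
    mapping of gene-expression fold changes onto reaction bounds through
    gene-protein-reaction (GPR) rules, and the CoreReg procedure that
    iteratively extracts hierarchical core sets of reactions whose bound
    contraction alone reproduces the flux ranges of a fully regulated
    model.  Includes simulation presets for acidogenic and solventogenic
    fermentation phases, gene-deletion analysis, yield-space mapping, and
    seed-deterministic synthetic network generators with brute-force
    oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
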