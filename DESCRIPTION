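Package: nmtqsar
Title: GA-MLR QSAR Workflow for N-Myristoyltransferase Inhibition by
    Nitrogen Heterocycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end quantitative structure-activity relationship
    (QSAR) workflow for human N-myristoyltransferase (Hs-NMT) inhibition
    by nitrogen heterocycles. Prepares charged 3D conformers from SMILES
    (via OpenBabel, MMFF94), computes charge-binned solvent-accessible
    surface area and atom-environment frequency descriptors including the
    five published model descriptors (all_HASA2, C_AbSA, fNH4B, fringNH2A,
    flipoH3B), prunes descriptor pools by objective feature selection,
    searches fixed-size descriptor subsets with a genetic algorithm scored
    by leave-one-out Q2, and validates multiple-linear-regression models
    with the full internal/external statistics suite (Q2F1-F3, CCC, r2m,
    Y-randomization, Williams-plot applicability domain). Ships the two
    published five-descriptor models for prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (>= 3.0) command line tools (obabel,
    obenergy) for MMFF94 optimization and charges; Python with RDKit for
    the seeded 3D embedding step.
Config/testthat/edition: 3
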