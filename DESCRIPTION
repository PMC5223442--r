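Package: qsarpharm
Title: Grid-Field 3D-QSAR and Pharmacophore Screening for Congeneric Ligand Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ligand-based virtual-screening toolkit: molecular-field (CoMFA-style)
    steric and electrostatic grid descriptors with Gasteiger-Marsili charges,
    stepwise-forward partial-least-squares 3D-QSAR with full internal, external
    and Y-randomization validation, common-pharmacophore hypothesis generation
    and scoring (site, vector, volume, selectivity, survival), k-of-n
    pharmacophore library screening with fitness ranking, and screening-quality
    statistics (enrichment factor, goodness-of-hit, ROC/AUC). Includes a
    synthetic congeneric-series and actives/decoys library generator so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    yaml,
    methods,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
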