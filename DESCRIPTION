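Package: tcaQSPR
Title: Hydrogen-Aware Distance-Based Topological Indices and QSPR Models
    for Tricyclic Antidepressants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes five distance- and detour-based topological indices
    (Wiener, hyper-Wiener, Harary, detour, detour-Harary) on molecular
    graphs built from SMILES under two hydrogen representations
    (H-suppressed heavy-atom skeleton and all-hydrogen), ships the curated
    fifteen-drug tricyclic-antidepressant study dataset with six
    physicochemical properties, and relates indices to properties through
    Pearson correlation, single-descriptor linear regression and
    RBF-kernel support vector regression with grid-search hyperparameter
    tuning under 5-fold cross-validation. Detour (longest simple path)
    distances are computed exactly via block-cut-tree decomposition.
    Includes a synthetic generator for molecule-like graphs and property
    vectors, and a reproduction driver that emits the study's tables as
    machine-readable CSV together with a discrepancy report for printed
    reference rows that are inconsistent with their stated construction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
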