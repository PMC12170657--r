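# tcaQSPR

Hydrogen-aware distance-based topological indices and QSPR models for
fifteen tricyclic-antidepressant (TCA) drugs.

## What it does, and for whom

QSPR (quantitative structure-property relationship) modelling predicts
physicochemical properties of drug candidates from numeric descriptors
of molecular structure, sparing measurement time and cost.  This package
is for cheminformaticians and graph-theory-minded modellers who want a
fully reproducible, offline implementation of a hydrogen-representation
study: every descriptor is computed on **two** graphs per molecule — the
H-suppressed heavy-atom skeleton and the all-hydrogen graph in which
every hydrogen is an explicit pendant vertex — and both descriptor sets
are related to six properties (boiling point, enthalpy of vaporization,
flash point, molar refractivity, polarizability, molar volume).

The five descriptors are distance-based graph invariants.  With
`d(a,b)` the shortest-path distance and `D(a,b)` the detour distance
(longest simple path) between vertices, summing over unordered pairs:

    W  = Σ d(a,b)                 (Wiener)
    WW = Σ (d(a,b) + d(a,b)²)/2   (hyper-Wiener)
    H  = Σ 1/d(a,b)               (Harary)
    D  = Σ D(a,b)                 (detour)
    DH = Σ 1/D(a,b)               (detour-Harary)

Detour distances are computed **exactly** by block-cut-tree
decomposition: within each biconnected block, longest paths by
exhaustive DFS under a budget; across blocks, segments add along the
unique block path.  Models are single-descriptor ordinary least squares
(full data, `R² = r²` identity preserved) and RBF-kernel support vector
regression tuned by grid search (`C ∈ {10,50,100,500}`,
`ε ∈ {0.1,…,0.5}`, gamma ∈ {scale, auto}) with 5-fold cross-validation
on an 80/20 split.

SMILES parsing is delegated to Open Babel (ChemmineOB); graph machinery
to igraph; the SVR dual solver to libsvm (e1071).  The detour algorithm,
the indices, the metrics and the tuning protocol are implemented here.

## Worked example

```r
library(tcaQSPR)

dzm <- parseSmiles("CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1", "Diazepam", "DZM")
dzm
#> Molecule: Diazepam (DZM)
#>   SMILES: CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1
#>   20 heavy atoms, 22 bonds, 13 implicit hydrogens [C16H13ClN2O]

g <- buildGraph(dzm, "all-h")
g
#> MolecularGraph (all-h): 33 vertices, 35 edges, cyclomatic number 3

round(indexVector(g), 4)
#>         W        WW         H         D        DH
#> 2497.0000 8380.0000  154.1603 5741.0000   71.3523

drugs <- loadDrugs()        # 15 records, SMILES locked by formula check
f <- fitLR(loadReferenceIndices("heavy")$H, drugs$BP)
f
#> LRFit: y = -19.4084 + 6.09307 x  (n = 15)
#>   R2 = 0.6692, RMSE = 37.3973
```

The diazepam all-hydrogen Wiener index 2497 and the Harary/boiling-point
linear fit (R² 0.6692, RMSE 37.3973) are the published reference values;
the heavy-mode diazepam vector is (726, 2077, 69.4905, 1901, 24.9069).
`reproduce("out-dir", seed = 42)` writes the complete bundle: index
tables for both modes, 5×6 correlation matrices, LR and SVR reports with
per-property best indices and chosen hyperparameters, actual-vs-predicted
values per property, a discrepancy report for the published heavy-mode
rows that are inconsistent with their stated construction (see the
vignette), and a JSON manifest.  Equal seeds give byte-identical bundles.

A thin command-line wrapper with subcommands (`compute-indices`,
`correlate`, `fit-lr`, `tune-svr`, `reproduce`) ships in
`inst/scripts/tcaqspr.R`.

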