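Package: enskit
Title: Analysis Toolkit for Submucosal Enteric Neuron Single-Cell, Calcium and 3D Proximity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-stage analysis pipeline for single-cell RNA-seq of mouse
    submucosal enteric neurons and companion functional assays. Provides
    iterative quality control (global thresholds, per-cluster percentile
    trimming, artificial-doublet pANN scoring, marker-driven contaminant
    exclusion), normalization and highly-variable-gene selection with
    exclusion lists, PCA and SNN-graph Louvain clustering, marker ranking and
    signature-based class annotation, rule-based sex inference and masked
    cross-dataset label transfer, ligand-receptor communication scoring with
    truncated means and a permutation null, epoch-based calcium-response
    classification for mechanical-deformation protocols, and 3D shortest
    distance quantification between nerve-fiber varicosities and cell
    surfaces. Ships synthetic-data generators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
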