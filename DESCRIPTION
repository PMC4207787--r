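Package: dimerstab
Title: Ensemble-Based Discovery of Protein Homo-Dimer Interface Stabilizers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of an ensemble-based virtual
    screening protocol for small-molecule stabilizers of a destabilized
    protein homo-dimer. Covers multi-model PDB structure handling, Kabsch
    superposition with RMSD/RMSF/B-factor trajectory validation, Ward
    hierarchical clustering of binding-site conformations from all-atom
    RMSD matrices, grid-probe pocket detection with druggability
    descriptors, PPI-adapted physicochemical compound filtering with
    circular-fingerprint diversity and scaffold clustering, consensus
    rank-intersection of per-engine docking score tables, and rigid versus
    relaxed binding free-energy rescoring over per-snapshot energy
    trajectories. A deterministic synthetic-data generator with planted
    ground truth makes every stage testable end-to-end without external
    trajectories, vendor libraries, or docking engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    ChemmineR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
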