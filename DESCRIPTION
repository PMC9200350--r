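Package: scpipeline
Title: Single-Cell RNA-Seq Analysis Pipeline from Counts to Drug Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular, reproducible workflow for single-sample droplet-based
    single-cell RNA-seq analysis of tumor biopsies: quality-control filtering of
    genes and cells, variance-stabilizing normalization via analytic Pearson
    residuals with cell-cycle correction, kNN-graph community clustering with a
    minimum cluster size, hierarchical marker-list cell typing with explicit
    unknown and uncertain calls, per-cluster differential expression between
    tumor clusters and the non-malignant microenvironment, competitive and
    per-cell rank-based gene-set analysis, and directed in-silico drug-candidate
    identification from offline drug-gene interaction and clinical-evidence
    snapshots. Includes a synthetic-data generator with planted ground truth for
    every stage and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    RANN,
    uwot,
    matrixStats,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
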