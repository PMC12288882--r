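Package: declust
Title: Cluster-Based Cell-Type Deconvolution of Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates cell-type composition of spatial transcriptomics
    (ST) spots by a cluster-based strategy: spots are grouped into
    spatially coherent, transcriptionally similar clusters (hierarchical
    clustering, DBSCAN spatial sub-clustering, seeded region growing),
    per-cluster pseudo-bulk profiles are deconvolved against a marker-gene
    reference built from annotated scRNA-seq via non-negativity-constrained
    ordinary least squares, and cluster-level proportions are propagated
    back to spots. Includes multinomial spot simulators with
    ligand-receptor co-enrichment, a synthetic fixture generator, and
    simulation metrics plus a spatially stratified cross-validation
    harness for real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
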