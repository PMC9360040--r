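Package: cellgraphkit
Title: Graph-Centric, Chunked Analysis of Single-Cell Genomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Memory-frugal, graph-centric toolkit for single-cell RNA-seq and
    ATAC-seq count matrices. Count matrices are stored as compressed dense
    chunks on disk and streamed block-wise through cell filtering, library-size
    and TF-IDF normalisation, trend-corrected highly variable gene selection,
    streamed PCA/LSI and exact or approximate k-nearest-neighbour graph
    construction with UMAP-style edge-weight smoothing. The cell-cell
    neighbourhood graph drives Leiden clustering, Paris hierarchical
    clustering via the nearest-neighbour chain, topology-assisted
    downsampling (seed cells connected by a prize-collecting Steiner tree),
    and reference-anchored KNN mapping with CORAL covariance alignment,
    mapping scores and label transfer, plus rank-based marker scoring and
    graph/embedding evaluation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    ape,
    testthat (>= 3.0.0),
    RcppHNSW,
    uwot,
    rhdf5,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
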