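#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t rowSums colSums crossprod tcrossprod Diagonal drop0
#' @importFrom stats kmeans lowess approx qnorm sd var cor rnbinom runif rnorm rlnorm rexp rgamma quantile median setNames
#' @importFrom utils read.delim write.table head tail
NULL

#' AssayStore: a chunked, compressed on-disk count matrix
#'
#' An `AssayStore` points at one assay of an on-disk store directory. The
#' count matrix (cells as rows, features as columns) is split into a grid of
#' dense chunks, each compressed and written as its own file, so that any
#' downstream operation can stream row blocks without ever materialising the
#' full matrix. Cell-level attributes live at the store root (shared across
#' assays); feature-level attributes live under the assay group.
#'
#' @slot path store directory.
#' @slot assay assay name (group under `assays/`).
#' @slot dims integer vector `c(n_cells, n_features)`.
#' @slot chunkShape integer vector, rows x columns per chunk.
#' @slot compressed logical; chunks are gzip-compressed on disk.
#'
#' @seealso [createStore()], [readCounts()], [iterChunks()], [exportSubset()]
#' @export
setClass("AssayStore",
  representation(
    path = "character",
    assay = "character",
    dims = "integer",
    chunkShape = "integer",
    compressed = "logical"
  )
)

setValidity("AssayStore", function(object) {
  msg <- NULL
  if (length(object@dims) != 2L || any(object@dims < 0L))
    msg <- c(msg, "dims must be two non-negative integers")
  if (length(object@chunkShape) != 2L || any(object@chunkShape < 1L))
    msg <- c(msg, "chunkShape must be two positive integers")
  if (!dir.exists(object@path))
    msg <- c(msg, sprintf("store directory '%s' does not exist", object@path))
  if (is.null(msg)) TRUE else msg
})

#' ReducedMatrix: cells in a low-dimensional space
#'
#' Holds the per-cell coordinates produced by streamed PCA or LSI together
#' with everything needed to transform new cells into the same space: the
#' standard-scaling statistics fitted on the training cells and the feature
#' loadings.
#'
#' @slot coords cells x d coordinate matrix.
#' @slot method `"pca"` or `"lsi"`.
#' @slot d number of dimensions.
#' @slot center,scale per-feature scaling statistics (length 0 for LSI).
#' @slot loadings features x d loading matrix.
#' @slot featureIds ids of the features the reduction was fitted on.
#' @export
setClass("ReducedMatrix",
  representation(
    coords = "matrix",
    method = "character",
    d = "integer",
    center = "numeric",
    scale = "numeric",
    loadings = "matrix",
    featureIds = "character"
  )
)

setValidity("ReducedMatrix", function(object) {
  msg <- NULL
  if (object@d < 2L) msg <- c(msg, "d must be >= 2")
  if (ncol(object@coords) != object@d) msg <- c(msg, "coords must have d columns")
  if (any(!is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (!object@method %in% c("pca", "lsi")) msg <- c(msg, "method must be 'pca' or 'lsi'")
  if (is.null(msg)) TRUE else msg
})

#' NeighbourGraph: the cell-cell KNN graph
#'
#' The central object of the package: per-cell neighbour indices, raw
#' Euclidean distances, and (after [smoothEdgeWeights()]) continuous edge
#' weights in (0, 1]. All downstream operations (clustering, downsampling,
#' embedding, evaluation) consume this graph. The directed k-neighbour lists
#' are stored; [symmetrizedAdjacency()] provides the undirected fuzzy-union
#' view used by graph algorithms.
#'
#' @slot knnIdx cells x k integer matrix of neighbour indices (no self loops).
#' @slot knnDist cells x k matrix of Euclidean distances, non-decreasing per row.
#' @slot weights cells x k smoothed edge weights in (0, 1]; 0 rows x 0 cols
#'   until [smoothEdgeWeights()] has been run.
#' @slot k number of neighbours.
#' @slot recall fraction of cells returned as their own nearest neighbour
#'   during the self-query check (1 for the exact backend).
#' @slot backend `"exact"` or `"hnsw"`.
#' @export
setClass("NeighbourGraph",
  representation(
    knnIdx = "matrix",
    knnDist = "matrix",
    weights = "matrix",
    k = "integer",
    recall = "numeric",
    backend = "character"
  )
)

setValidity("NeighbourGraph", function(object) {
  msg <- NULL
  n <- nrow(object@knnIdx)
  if (!identical(dim(object@knnIdx), dim(object@knnDist)))
    msg <- c(msg, "knnIdx and knnDist must have identical dimensions")
  if (ncol(object@knnIdx) != object@k) msg <- c(msg, "knnIdx must have k columns")
  if (n > 0 && any(object@knnIdx == seq_len(n))) msg <- c(msg, "self loops are not allowed")
  if (n > 0 && object@k > 1 &&
      any(object@knnDist[, -1, drop = FALSE] - object@knnDist[, -object@k, drop = FALSE] < -1e-9))
    msg <- c(msg, "distances must be non-decreasing along each row")
  if (nrow(object@weights) > 0) {
    if (!identical(dim(object@weights), dim(object@knnIdx)))
      msg <- c(msg, "weights must match knnIdx dimensions")
    if (any(object@weights <= 0 | object@weights > 1 + 1e-12))
      msg <- c(msg, "weights must lie in (0, 1]")
  }
  if (object@recall < 0 || object@recall > 1) msg <- c(msg, "recall must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' ParisDendrogram: binary merge tree from Paris graph clustering
#'
#' Merges are stored in non-decreasing height order (the order produced by
#' sorting the nearest-neighbour-chain output, which is valid because the
#' node-pair sampling distance is reducible). Nodes `1..n` are leaves (cells);
#' node `n + i` is the cluster created by merge `i`.
#'
#' @slot merges (n-1) x 2 integer matrix of merged node ids.
#' @slot heights merge heights (distances), non-decreasing; `Inf` joins
#'   disconnected components under a synthetic root.
#' @slot nLeaves number of cells.
#' @slot leafIds optional cell identifiers.
#' @export
setClass("ParisDendrogram",
  representation(
    merges = "matrix",
    heights = "numeric",
    nLeaves = "integer",
    leafIds = "character"
  )
)

setValidity("ParisDendrogram", function(object) {
  msg <- NULL
  n <- object@nLeaves
  if (n >= 2 && (nrow(object@merges) != n - 1L || length(object@heights) != n - 1L))
    msg <- c(msg, "a dendrogram over n leaves must contain exactly n-1 merges")
  if (length(object@heights) > 1 &&
      isTRUE(any(diff(object@heights) < -1e-9)))  # Inf-Inf diffs are NaN, not decreases
    msg <- c(msg, "heights must be non-decreasing in merge order")
  if (any(object@heights < 0)) msg <- c(msg, "heights must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' SketchResult: outcome of topology-assisted downsampling
#'
#' @slot seeds indices of seed cells (landmarks chosen per cluster).
#' @slot selected indices of all selected cells (seeds plus Steiner cells).
#' @slot selectedEdges m x 2 integer matrix of tree edges over selected cells.
#' @slot perCluster data.frame of per-cluster bookkeeping (size, median NND,
#'   median NC, sampling rate, seeds requested/selected).
#' @export
setClass("SketchResult",
  representation(
    seeds = "integer",
    selected = "integer",
    selectedEdges = "matrix",
    perCluster = "data.frame"
  )
)

setValidity("SketchResult", function(object) {
  msg <- NULL
  if (anyDuplicated(object@selected)) msg <- c(msg, "selected cells must be unique")
  if (is.null(msg)) TRUE else msg
})

#' MappingResult: target-to-reference KNN edges
#'
#' For every target cell, its k nearest reference cells in the reference
#' reduced space, the Euclidean distances, and the mapping weights
#' `W = 1 / (ln(D + 1) + 1)`.
#'
#' @slot knnIdx targets x k reference indices.
#' @slot knnDist targets x k distances.
#' @slot weights targets x k mapping weights in (0, 1].
#' @slot nRef number of reference cells.
#' @slot k neighbours per target.
#' @slot targetIds optional target cell ids.
#' @export
setClass("MappingResult",
  representation(
    knnIdx = "matrix",
    knnDist = "matrix",
    weights = "matrix",
    nRef = "integer",
    k = "integer",
    targetIds = "character"
  )
)

setValidity("MappingResult", function(object) {
  msg <- NULL
  if (!identical(dim(object@knnIdx), dim(object@knnDist)) ||
      !identical(dim(object@knnIdx), dim(object@weights)))
    msg <- c(msg, "knnIdx, knnDist and weights must share dimensions")
  if (length(object@weights) && any(object@weights <= 0 | object@weights > 1 + 1e-12))
    msg <- c(msg, "weights must lie in (0, 1]")
  if (length(object@knnIdx) && (any(object@knnIdx < 1) || any(object@knnIdx > object@nRef)))
    msg <- c(msg, "reference indices out of range")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "AssayStore", function(object) {
  cat(sprintf("AssayStore '%s' at %s\n", object@assay, object@path))
  cat(sprintf("  %d cells x %d features, chunks %d x %d%s\n",
              object@dims[1], object@dims[2],
              object@chunkShape[1], object@chunkShape[2],
              if (object@compressed) " (compressed)" else ""))
})

setMethod("show", "ReducedMatrix", function(object) {
  cat(sprintf("ReducedMatrix (%s): %d cells x %d dims\n",
              object@method, nrow(object@coords), object@d))
})

setMethod("show", "NeighbourGraph", function(object) {
  cat(sprintf("NeighbourGraph: %d cells, k = %d, backend = %s, recall = %.3f\n",
              nrow(object@knnIdx), object@k, object@backend, object@recall))
  cat(if (nrow(object@weights) > 0) "  edge weights: smoothed\n" else "  edge weights: not yet smoothed\n")
})

setMethod("show", "ParisDendrogram", function(object) {
  cat(sprintf("ParisDendrogram: %d leaves, %d merges, height range [%.4g, %.4g]\n",
              object@nLeaves, nrow(object@merges),
              min(object@heights), max(object@heights)))
})

setMethod("show", "SketchResult", function(object) {
  cat(sprintf("SketchResult: %d seeds, %d selected cells, %d tree edges\n",
              length(object@seeds), length(object@selected), nrow(object@selectedEdges)))
})

setMethod("show", "MappingResult", function(object) {
  cat(sprintf("MappingResult: %d target cells mapped onto %d reference cells (k = %d)\n",
              nrow(object@knnIdx), object@nRef, object@k))
})
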