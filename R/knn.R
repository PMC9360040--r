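# KNN index, graph construction, UMAP-style edge-weight smoothing, and the
# k-means initial embedding.

#' Build a nearest-neighbour index over reduced coordinates
#'
#' Backends: `"exact"` stores the coordinates and answers queries by
#' brute-force blockwise Euclidean search (the oracle backend; recall is 1 by
#' construction on distinct points); `"hnsw"` delegates to the RcppHNSW
#' approximate index (graph degree 48, construction beam 200, query beam 100)
#' when that package is installed.
#'
#' @param coords cells x d numeric matrix (e.g. `coords(reduced)`).
#' @param backend `"exact"` or `"hnsw"`.
#' @param M,ef_construction,ef HNSW hyperparameters.
#' @param seed seed handed to the approximate backend.
#' @return a `KnnIndex` object (S3), save/load with [saveKnnIndex()].
#' @export
buildKnnIndex <- function(coords, backend = c("exact", "hnsw"),
                          M = 48L, ef_construction = 200L, ef = 100L,
                          seed = 42L) {
  backend <- match.arg(backend)
  coords <- .asDense(coords)
  idx <- list(backend = backend, coords = coords,
              params = list(M = M, ef_construction = ef_construction, ef = ef,
                            seed = seed))
  if (backend == "hnsw") {
    if (!requireNamespace("RcppHNSW", quietly = TRUE))
      stop("the 'hnsw' backend requires the RcppHNSW package, which is not installed",
           call. = FALSE)
    set.seed(seed)
    idx$ann <- RcppHNSW::hnsw_build(coords, distance = "euclidean",
                                    M = M, ef = ef_construction)
  }
  class(idx) <- "KnnIndex"
  idx
}

#' Query a nearest-neighbour index
#'
#' @param index a `KnnIndex` from [buildKnnIndex()].
#' @param query query coordinates (cells x d).
#' @param k neighbours per query point.
#' @param block query rows processed per block (exact backend).
#' @return list with `idx` (queries x k) and `dist` (Euclidean), sorted by
#'   non-decreasing distance; ties broken by lower index.
#' @export
queryKnnIndex <- function(index, query, k, block = 1000L) {
  query <- .asDense(query)
  k <- .assertScalarCount(k, "k")
  if (ncol(query) != ncol(index$coords))
    stop("query dimensionality does not match the index", call. = FALSE)
  if (k > nrow(index$coords))
    stop("k exceeds the number of indexed points", call. = FALSE)
  if (index$backend == "hnsw") {
    res <- RcppHNSW::hnsw_search(query, index$ann, k = k, ef = max(index$params$ef, k))
    return(list(idx = res$idx, dist = res$dist))
  }
  nq <- nrow(query)
  outIdx <- matrix(0L, nq, k)
  outDist <- matrix(0, nq, k)
  if (nq == 0) return(list(idx = outIdx, dist = outDist))
  for (b in .rowBlocks(nq, block)) {
    rows <- b[1]:b[2]
    D <- .crossDist(query[rows, , drop = FALSE], index$coords)
    for (r in seq_along(rows)) {
      ord <- order(D[r, ], seq_len(ncol(D)))[seq_len(k)]
      outIdx[rows[r], ] <- ord
      outDist[rows[r], ] <- D[r, ord]
    }
  }
  list(idx = outIdx, dist = outDist)
}

#' Save / load a KnnIndex
#'
#' The exact index serialises directly; the HNSW index is persisted as its
#' training coordinates plus hyperparameters and rebuilt on load.
#'
#' @param index a `KnnIndex`.
#' @param path file path.
#' @return `loadKnnIndex()`: the restored `KnnIndex`.
#' @export
saveKnnIndex <- function(index, path) {
  payload <- index[c("backend", "coords", "params")]
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveKnnIndex
#' @export
loadKnnIndex <- function(path) {
  payload <- readRDS(path)
  buildKnnIndex(payload$coords, backend = payload$backend,
                M = payload$params$M, ef_construction = payload$params$ef_construction,
                ef = payload$params$ef, seed = payload$params$seed)
}

#' Build the cell-cell KNN graph
#'
#' Queries the index for `k + 1` neighbours per cell, notes whether each cell
#' is returned as its own nearest neighbour (summarised as the recall value,
#' measured before self-removal), removes the self match (or, on an
#' approximate miss, the last neighbour), and returns the directed
#' k-neighbour lists with Euclidean distances.
#'
#' @param reduced a [ReducedMatrix-class] or a plain coordinate matrix.
#' @param k neighbours per cell (`k < n_cells`).
#' @param backend `"exact"` (default) or `"hnsw"`.
#' @param seed passed to the backend.
#' @param index_path if non-`NULL`, the trained index is persisted here for
#'   reuse (e.g. reference mapping).
#' @return a [NeighbourGraph-class] (weights not yet smoothed).
#' @seealso [smoothEdgeWeights()], [symmetrizedAdjacency()]
#' @export
buildKnnGraph <- function(reduced, k, backend = c("exact", "hnsw"),
                          seed = 42L, index_path = NULL) {
  backend <- match.arg(backend)
  coordsM <- if (is(reduced, "ReducedMatrix")) coords(reduced) else .asDense(reduced)
  n <- nrow(coordsM)
  k <- .assertScalarCount(k, "k")
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of cells (%d)", k, n),
                   call. = FALSE)
  index <- buildKnnIndex(coordsM, backend = backend, seed = seed)
  if (!is.null(index_path)) saveKnnIndex(index, index_path)
  res <- queryKnnIndex(index, coordsM, k + 1L)

  knnIdx <- matrix(0L, n, k)
  knnDist <- matrix(0, n, k)
  hits <- logical(n)
  for (i in seq_len(n)) {
    ids <- res$idx[i, ]; ds <- res$dist[i, ]
    hits[i] <- ids[1] == i || (any(ids == i) && ds[which(ids == i)[1]] <= ds[1] + 1e-12)
    selfPos <- which(ids == i)[1]
    if (is.na(selfPos)) {
      ids <- ids[seq_len(k)]; ds <- ds[seq_len(k)]   # approximate self miss
    } else {
      ids <- ids[-selfPos]; ds <- ds[-selfPos]
    }
    knnIdx[i, ] <- ids
    knnDist[i, ] <- ds
  }
  new("NeighbourGraph", knnIdx = knnIdx, knnDist = knnDist,
      weights = matrix(0, 0, 0), k = k, recall = mean(hits), backend = backend)
}

#' UMAP-style edge-weight smoothing
#'
#' Converts each cell's neighbour distances into weights in (0, 1]:
#' `w_i = exp(-max(0, d_i - rho) / sigma)` with `rho` the distance to the
#' nearest neighbour (local connectivity 1) and `sigma` found per cell by
#' bisection so the weights sum to `log2(k)` (tolerance 1e-5, at most 64
#' iterations). The nearest neighbour always gets weight 1. When all k
#' distances are equal the target is unreachable and `sigma` clamps to its
#' lower bound, yielding all-1 weights.
#'
#' @param graph a [NeighbourGraph-class] with distances.
#' @return the graph with its `weights` slot filled.
#' @export
smoothEdgeWeights <- function(graph) {
  d <- knnDistances(graph)
  n <- nrow(d); k <- ncol(d)
  rho <- d[, 1]
  excess <- d - rho
  excess[excess < 0] <- 0
  target <- log2(k)

  lo <- rep(1e-12, n)
  hi <- rep(1, n)
  psi <- function(sigma) rowSums(exp(-excess / sigma))
  # grow hi until the target is bracketed (psi is increasing in sigma)
  for (it in 1:64) {
    need <- psi(hi) < target
    if (!any(need)) break
    hi[need] <- hi[need] * 2
  }
  for (it in 1:64) {
    mid <- (lo + hi) / 2
    val <- psi(mid)
    up <- val < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(hi - lo) < 1e-8) break
  }
  sigma <- (lo + hi) / 2
  w <- exp(-excess / sigma)
  w[w > 1] <- 1
  w[w < 1e-12] <- 1e-12  # keep weights inside (0, 1] even when sigma clamps
  w[, 1] <- 1  # d == rho => exp(0)
  graph@weights <- w
  validObject(graph)
  graph
}

#' @rdname symmetrizedAdjacency
#' @export
setMethod("symmetrizedAdjacency", "NeighbourGraph", function(x, ...) {
  n <- nCells(x)
  w <- if (nrow(x@weights) > 0) as.vector(x@weights) else {
    # unsmoothed graphs fall back to binary edges
    rep(1, length(x@knnIdx))
  }
  i <- rep(seq_len(n), times = x@k)
  j <- as.vector(x@knnIdx)
  A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  At <- Matrix::t(A)
  # fuzzy union: w1 + w2 - w1*w2 on reciprocated edges
  S <- A + At - A * At
  Matrix::drop0(S)
})

#' @rdname symmetrizedAdjacency
#' @export
setMethod("symmetrizedAdjacency", "Matrix", function(x, ...) {
  if (!Matrix::isSymmetric(x)) stop("adjacency matrix must be symmetric", call. = FALSE)
  methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix")
})

#' K-means initial embedding
#'
#' Fits k-means with `c` centroids on the reduced coordinates, reduces the
#' c x d centroid matrix by a second PCA to `dim` dimensions, and assigns
#' every cell the projected coordinates of its centroid — so cells sharing a
#' centroid share identical initial coordinates.
#'
#' @param reduced a [ReducedMatrix-class] or coordinate matrix.
#' @param c number of centroids (2 <= c <= n_cells); default
#'   `min(100, floor(n/10))`, floored at 2.
#' @param dim 2 or 3.
#' @param seed seed for k-means.
#' @return list with `centroids` (c x d), `coords` (cells x dim),
#'   `cluster_of_cell` (per-cell centroid id).
#' @export
initialEmbedding <- function(reduced, c = NULL, dim = 2L, seed = 42L) {
  X <- if (is(reduced, "ReducedMatrix")) coords(reduced) else .asDense(reduced)
  n <- nrow(X)
  c <- c %||% max(2L, min(100L, floor(n / 10)))
  if (!dim %in% c(2L, 3L)) stop("'dim' must be 2 or 3", call. = FALSE)
  if (c < 2 || c > n) stop("'c' must lie in [2, n_cells]", call. = FALSE)
  ux <- unique(X)
  c <- min(c, nrow(ux))
  set.seed(seed)
  if (c == nrow(ux)) {
    # saturated: every distinct point is its own centroid
    cent <- ux
    cluster <- match(apply(X, 1, paste, collapse = "\r"),
                     apply(ux, 1, paste, collapse = "\r"))
  } else {
    km <- suppressWarnings(kmeans(X, centers = c, iter.max = 100L, nstart = 1L))
    cent <- km$centers
    cluster <- km$cluster
  }
  mu <- colMeans(cent)
  centC <- sweep(cent, 2, mu)
  eg <- eigen(crossprod(centC) / max(1, nrow(centC) - 1), symmetric = TRUE)
  V <- .fixSigns(eg$vectors[, seq_len(min(dim, ncol(centC))), drop = FALSE])
  proj <- centC %*% V
  if (ncol(proj) < dim) proj <- cbind(proj, matrix(0, nrow(proj), dim - ncol(proj)))
  list(centroids = cent, coords = proj[cluster, , drop = FALSE],
       cluster_of_cell = cluster)
}
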