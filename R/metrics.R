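# Rank-based marker scoring and evaluation statistics for embeddings,
# subsampling and cluster geometry. All functions here are pure: inputs are
# never mutated and identical inputs give identical outputs.

#' Rank-based marker scores
#'
#' For every feature, cells are ranked by the feature's normalised value
#' (average ranks on ties), the ranks are averaged within each cluster, and
#' each cluster's mean rank is divided by the sum of mean ranks over all
#' clusters — so scores lie in \[0, 1\] and sum to 1 across clusters for
#' every feature. High scores flag cluster-specific markers.
#'
#' @param x normalised values: an [AssayStore-class] of normalised counts or
#'   a matrix (cells x features). Store input is streamed; ranks are computed
#'   feature-wise over all cells, so columns are assembled across blocks.
#' @param labels integer cluster labels per cell (every cluster non-empty).
#' @param block_fun optional `function(block, rows)` applied per streamed
#'   block before ranking (e.g. normalisation of a raw-count store).
#' @return features x clusters matrix of scores.
#' @export
markerScores <- function(x, labels, block_fun = NULL) {
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  if (min(table(factor(labels, levels = cl))) == 0) stop("empty cluster", call. = FALSE)
  if (is(x, "AssayStore")) {
    block_fun <- block_fun %||% function(block, rows) block
    m <- matrix(0, nCells(x), nFeatures(x))
    streamBlocks(x, x@chunkShape[1], function(block, rows) {
      m[rows, ] <<- block_fun(block, rows)
      NULL
    })
    x <- m
  } else {
    x <- .asDense(x)
    if (!is.null(block_fun)) x <- block_fun(x, seq_len(nrow(x)))
  }
  if (length(labels) != nrow(x)) stop("labels must cover all cells", call. = FALSE)
  ranks <- apply(x, 2, rank)                      # average ranks on ties
  meanRanks <- rowsum(ranks, labels) / as.vector(table(labels))
  scores <- t(meanRanks) / colSums(meanRanks)     # features x clusters
  colnames(scores) <- as.character(cl)
  scores
}

#' Average centroid distance (ACD)
#'
#' Mean Euclidean distance of cells from their cluster centroid in the
#' embedding; lower values mean tighter, better-localised clusters.
#'
#' @param coords cells x 2 (or 3) embedding coordinates.
#' @param labels cluster labels per cell.
#' @return a single number.
#' @export
averageCentroidDistance <- function(coords, labels) {
  coords <- .asDense(coords)
  if (length(labels) != nrow(coords)) stop("labels must cover all cells", call. = FALSE)
  labels <- as.integer(factor(labels))
  cent <- rowsum(coords, labels) / as.vector(table(labels))
  mean(sqrt(rowSums((coords - cent[labels, , drop = FALSE])^2)))
}

#' Log2 cluster enrichment of a selection
#'
#' `log2((cluster share among selected) / (cluster share overall))`:
#' positive values mean the cluster's proportion grew after subsampling.
#' Clusters absent from the selection report `-Inf` with a warning.
#'
#' @param labels cluster labels for all cells.
#' @param selected_mask logical (or index vector) marking selected cells.
#' @return named numeric vector, one entry per cluster.
#' @export
clusterEnrichment <- function(labels, selected_mask) {
  if (!is.logical(selected_mask)) {
    idx <- selected_mask
    selected_mask <- rep(FALSE, length(labels))
    selected_mask[idx] <- TRUE
  }
  if (!any(selected_mask)) stop("selection is empty", call. = FALSE)
  cl <- sort(unique(as.integer(labels)))
  overall <- as.vector(table(factor(labels, levels = cl))) / length(labels)
  sel <- as.vector(table(factor(labels[selected_mask], levels = cl))) / sum(selected_mask)
  out <- log2(sel / overall)
  names(out) <- as.character(cl)
  if (any(!is.finite(out)))
    warning(sprintf("cluster(s) absent from the selection: %s",
                    paste(names(out)[!is.finite(out)], collapse = ", ")))
  out
}

#' Percentage of selected cells with non-zero degree among the selection
#'
#' The fraction (as a percentage) of selected cells that keep at least one
#' edge, in the original graph, to another selected cell — the standard
#' check that a subsample preserves graph connectivity rather than
#' scattering isolated cells.
#'
#' @param x a [NeighbourGraph-class] or symmetric sparse adjacency.
#' @param selected_mask logical or index vector of selected cells.
#' @return percentage in \[0, 100\].
#' @export
nonzeroDegreeFraction <- function(x, selected_mask) {
  A <- .binaryAdjacency(x)
  n <- nrow(A)
  if (!is.logical(selected_mask)) {
    idx <- selected_mask
    selected_mask <- rep(FALSE, n)
    selected_mask[idx] <- TRUE
  }
  if (!any(selected_mask)) stop("selection is empty", call. = FALSE)
  sub <- A[selected_mask, selected_mask, drop = FALSE]
  100 * mean(Matrix::rowSums(sub) > 0)
}

#' KNN preservation between graph and embedding
#'
#' For each cell, the overlap between its k graph neighbours and its k
#' nearest neighbours in the embedding (exact Euclidean search), averaged
#' over cells and divided by k.
#'
#' @param coords embedding coordinates (cells x dim).
#' @param graph a [NeighbourGraph-class]; its `k` is used.
#' @return fraction in \[0, 1\].
#' @export
knnPreservation <- function(coords, graph) {
  coords <- .asDense(coords)
  k <- graph@k
  n <- nCells(graph)
  if (nrow(coords) != n) stop("coords must cover all graph cells", call. = FALSE)
  idxEmb <- queryKnnIndex(buildKnnIndex(coords), coords, k + 1L)$idx
  overlap <- numeric(n)
  for (i in seq_len(n)) {
    emb <- setdiff(idxEmb[i, ], i)[seq_len(k)]
    overlap[i] <- length(intersect(graph@knnIdx[i, ], emb)) / k
  }
  mean(overlap)
}

#' Per-cluster Spearman correlation of two cluster-similarity matrices
#'
#' Compares cluster neighbourhood structure between the graph and an
#' embedding: both P x P similarity matrices (see
#' [clusterSimilarityGraph()]) are log2-transformed after adding a
#' pseudo-count of 1 (zeros are legitimate for disconnected pairs), and
#' Spearman's rho is computed between matched columns.
#'
#' @param graph_sim,embed_sim P x P similarity matrices over the same
#'   clusters in the same order; P >= 3.
#' @return numeric vector of per-cluster rho values.
#' @export
clusterSimilaritySpearman <- function(graph_sim, embed_sim) {
  if (!all(dim(graph_sim) == dim(embed_sim)))
    stop("similarity matrices must have identical dimensions", call. = FALSE)
  P <- ncol(graph_sim)
  if (P < 3) stop("rank correlation needs at least 3 clusters", call. = FALSE)
  a <- log2(graph_sim + 1)
  b <- log2(embed_sim + 1)
  vapply(seq_len(P), function(p) cor(a[, p], b[, p], method = "spearman"), 0)
}
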