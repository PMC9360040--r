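# Reference-anchored KNN mapping: common-total rescaling over reference
# HVGs, CORAL covariance alignment, projection onto the reference index,
# unified-graph spiking, mapping scores, and label transfer.

#' Rescale cells to a common total over the reference HVG set
#'
#' Second-round normalisation applied before mapping: for every cell (from
#' reference and target alike), the values of the reference-defined HVGs are
#' scaled so their sum equals `total` (default 1000). Cells with a zero sum
#' over the HVG set cannot be rescaled; they are excluded with a warning and
#' reported by id in the `excluded` attribute, never silently zero-filled.
#'
#' @param block values (e.g. raw or library-size-normalised counts),
#'   cells x features.
#' @param hvg_mask logical per feature marking the reference HVG set; or
#'   `NULL` if `block` is already restricted to the HVGs.
#' @param total common per-cell sum (default 1000).
#' @return matrix of rescaled values over the HVG columns only, with an
#'   `excluded` attribute (character ids of dropped cells).
#' @export
rescaleToCommonTotal <- function(block, hvg_mask = NULL, total = 1000) {
  block <- .asDense(block)
  if (total <= 0) stop("'total' must be positive", call. = FALSE)
  hv <- if (is.null(hvg_mask)) block else block[, hvg_mask, drop = FALSE]
  rs <- rowSums(hv)
  excluded <- character(0)
  if (any(rs == 0)) {
    excluded <- rownames(block)[rs == 0] %||% as.character(which(rs == 0))
    warning(sprintf("excluding %d cell(s) with zero sum over the HVG set: %s",
                    length(excluded), paste(head(excluded, 5), collapse = ", ")))
    hv <- hv[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  out <- hv * (total / rs)
  attr(out, "excluded") <- excluded
  out
}

# Symmetric matrix power via eigendecomposition, eigenvalues floored at 1e-8.
.symPow <- function(M, p) {
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-8)
  eg$vectors %*% (vals^p * t(eg$vectors))
}

#' CORAL domain-shift correction
#'
#' Correlation alignment between a reference (source) and a target matrix
#' over the same HVG set: both are standard-scaled per feature (each with
#' its own statistics), covariances are shrunk by adding `shrinkage` to the
#' diagonal, and the target is whitened with its own covariance and
#' recoloured with the reference's:
#' `A = Cov(S)^(1/2) %*% Cov(T)^(-1/2)`, `T_dc = T_scaled %*% t(A)`,
#' which makes `cov(T_dc)` match `cov(S_scaled)`. `literal = TRUE` instead
#' applies `A = Cov(S)^(1/2) %*% Cov(T)^(+1/2)` (both covariances to the
#' +1/2 power); this variant does not match covariances and is provided for
#' comparison only.
#'
#' @param S_resc reference rescaled matrix (cells x HVGs), see
#'   [rescaleToCommonTotal()]; columns must carry HVG ids if `T_resc` does.
#' @param T_resc target rescaled matrix over the same HVG set and order.
#' @param shrinkage ridge term added to both covariance diagonals (default 1).
#' @param literal use the +1/2 exponent variant.
#' @return list with `T_corrected` (target in the reference's scaled space),
#'   `S_scaled`, `A`, `cov_S`, `cov_T`.
#' @export
coralCorrect <- function(S_resc, T_resc, shrinkage = 1, literal = FALSE) {
  S_resc <- .asDense(S_resc); T_resc <- .asDense(T_resc)
  if (ncol(S_resc) != ncol(T_resc))
    stop("reference and target must share the HVG set", call. = FALSE)
  sn <- colnames(S_resc); tn <- colnames(T_resc)
  if (!is.null(sn) && !is.null(tn) && !identical(sn, tn)) {
    diffs <- union(setdiff(sn, tn), setdiff(tn, sn))
    stop(sprintf("HVG mismatch between reference and target: %s",
                 paste(head(c(diffs, if (!length(diffs)) "(same set, different order)"), 10),
                       collapse = ", ")), call. = FALSE)
  }
  zscore <- function(m) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    sweep(sweep(m, 2, mu), 2, sdv, `/`)
  }
  S_sc <- zscore(S_resc)
  T_sc <- zscore(T_resc)
  p <- ncol(S_sc)
  covS <- crossprod(S_sc) / (nrow(S_sc) - 1) + shrinkage * diag(p)
  covT <- crossprod(T_sc) / (nrow(T_sc) - 1) + shrinkage * diag(p)
  A <- .symPow(covS, 0.5) %*% .symPow(covT, if (literal) 0.5 else -0.5)
  list(T_corrected = T_sc %*% t(A), S_scaled = S_sc, A = A,
       cov_S = covS, cov_T = covT)
}

#' Map target cells onto a reference KNN index
#'
#' Projects target cells (already transformed into the reference reduced
#' space, or raw coordinates) onto the saved reference index and returns the
#' k nearest reference cells per target with distances `D` and weights
#' `W = 1 / (ln(D + 1) + 1)`, so `W = 1` exactly when `D = 0` and `W`
#' strictly decreases in `D`.
#'
#' @param ref_index a `KnnIndex` over the reference cells (see
#'   [buildKnnIndex()], [loadKnnIndex()]).
#' @param target_coords target cells x d matrix in the reference space.
#' @param k reference neighbours per target (default 11).
#' @return a [MappingResult-class].
#' @export
mapCells <- function(ref_index, target_coords, k = 11L) {
  target_coords <- .asDense(target_coords)
  k <- .assertScalarCount(k, "k")
  res <- queryKnnIndex(ref_index, target_coords, k)
  W <- 1 / (log(res$dist + 1) + 1)
  new("MappingResult", knnIdx = res$idx, knnDist = res$dist, weights = W,
      nRef = nrow(ref_index$coords), k = k,
      targetIds = rownames(target_coords) %||% character(0))
}

#' Spike the reference graph with mapped target cells
#'
#' Builds the unified graph used for co-embedding: reference-reference edges
#' are the (symmetrized) reference graph, untouched; every target node gets
#' exactly `top_m` edges to its nearest reference cells, all at the constant
#' `spike_weight`.
#'
#' @param ref_graph the reference [NeighbourGraph-class] (or adjacency).
#' @param mapping a [MappingResult-class] with `k >= top_m`.
#' @param top_m reference neighbours spiked per target (default 3).
#' @param spike_weight constant weight of target-reference edges (default 1).
#' @return symmetric sparse adjacency over `n_ref + n_target` nodes
#'   (reference nodes first).
#' @export
unifiedGraph <- function(ref_graph, mapping, top_m = 3L, spike_weight = 1) {
  top_m <- .assertScalarCount(top_m, "top_m")
  if (top_m > mapping@k)
    stop(sprintf("top_m (%d) exceeds the mapping's k (%d)", top_m, mapping@k),
         call. = FALSE)
  refAdj <- symmetrizedAdjacency(ref_graph)
  nr <- nrow(refAdj)
  nt <- nrow(mapping@knnIdx)
  n <- nr + nt
  if (nt == 0) return(refAdj)
  ti <- rep(nr + seq_len(nt), times = top_m)
  rj <- as.vector(mapping@knnIdx[, seq_len(top_m), drop = FALSE])
  el <- .edgeList(refAdj)
  Matrix::sparseMatrix(i = c(el$i, el$j, ti, rj), j = c(el$j, el$i, rj, ti),
                       x = c(el$w, el$w, rep(spike_weight, 2 * length(ti))),
                       dims = c(n, n))
}

#' Per-reference mapping scores
#'
#' `M_r = sum(W_rt over targets t that mapped to r) / N_T`; references never
#' hit by any target score 0. Optionally the scores are multiplied by
#' `multiplier` and transformed `ln(multiplier * M + 1)`.
#'
#' @param mapping a [MappingResult-class].
#' @param multiplier scalar applied before the log transform (default 1000).
#' @param log_transform apply `ln(multiplier * M + 1)` (default `FALSE`
#'   returns raw `M_r`).
#' @return numeric per-reference score.
#' @export
mappingScores <- function(mapping, multiplier = 1000, log_transform = FALSE) {
  nT <- nrow(mapping@knnIdx)
  if (nT == 0) stop("mapping contains no target cells", call. = FALSE)
  agg <- rowsum(as.vector(mapping@weights), as.vector(mapping@knnIdx))
  M <- numeric(mapping@nRef)
  M[as.integer(rownames(agg))] <- agg[, 1] / nT
  if (log_transform) M <- log(multiplier * M + 1)
  M
}

#' Label transfer from reference to target cells
#'
#' For each target, edge weights to its k mapped reference cells are summed
#' per reference class; the target is ascribed the class holding at least
#' `threshold` (default 50%) of the total weight, provided it is the unique
#' maximum — otherwise `NA`.
#'
#' @param mapping a [MappingResult-class].
#' @param ref_labels labels of the reference cells (character or factor).
#' @param threshold minimum weight fraction (default 0.5).
#' @return character vector of transferred labels (`NA` where unassigned).
#' @export
transferLabels <- function(mapping, ref_labels, threshold = 0.5) {
  ref_labels <- as.character(ref_labels)
  if (length(ref_labels) != mapping@nRef)
    stop("ref_labels must cover all reference cells", call. = FALSE)
  nT <- nrow(mapping@knnIdx)
  out <- rep(NA_character_, nT)
  for (t in seq_len(nT)) {
    cls <- ref_labels[mapping@knnIdx[t, ]]
    w <- tapply(mapping@weights[t, ], cls, sum)
    frac <- w / sum(w)
    mx <- max(frac)
    if (mx >= threshold - 1e-12 && sum(frac >= mx - 1e-12) == 1)
      out[t] <- names(frac)[which.max(frac)]
  }
  out
}
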