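# Streamed linear dimension reduction: PCA for scRNA-seq, LSI for scATAC-seq.
#
# Both reductions are computed from a single pass-oriented design: per-block
# normalisation (supplied by the caller), feature masking, then accumulation
# of second-moment information. For narrow matrices (<= `exact_threshold`
# selected features) the feature-space Gram/covariance matrix is accumulated
# exactly and eigendecomposed; for wider matrices a seeded randomized
# subspace iteration (block power method, 4 iterations, 10 oversampled
# directions) runs one streamed pass per iteration. Either way no pass ever
# holds more than one row block in memory.

# Deterministic sign convention: the entry with the largest magnitude in each
# loading column is made positive.
.fixSigns <- function(V) {
  s <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  s[s == 0] <- 1
  sweep(V, 2, s, `*`)
}

.orth <- function(X) qr.Q(qr(X))

# Top-d eigenvectors of the (implicit) p x p matrix C = sum_blocks t(Zb) Zb,
# where Zb are streamed blocks produced by blockFun(rows). One streamed pass
# per subspace iteration.
.streamedTopEigen <- function(blockStream, p, d, exact_threshold, seed, n_iter = 4L) {
  if (p <= exact_threshold) {
    C <- matrix(0, p, p)
    blockStream(function(Zb) C <<- C + crossprod(Zb))
    eg <- eigen(C, symmetric = TRUE)
    return(list(vectors = .fixSigns(eg$vectors[, seq_len(d), drop = FALSE]),
                values = eg$values[seq_len(d)]))
  }
  l <- min(p, d + 10L)
  set.seed(seed)
  V <- .orth(matrix(rnorm(p * l), p, l))
  for (it in seq_len(n_iter)) {
    G <- matrix(0, p, l)
    blockStream(function(Zb) G <<- G + crossprod(Zb, Zb %*% V))
    V <- .orth(G)
  }
  # Rayleigh-Ritz rotation inside the converged subspace
  G <- matrix(0, p, l)
  blockStream(function(Zb) G <<- G + crossprod(Zb, Zb %*% V))
  M <- crossprod(V, G)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  list(vectors = .fixSigns((V %*% eg$vectors)[, seq_len(d), drop = FALSE]),
       values = eg$values[seq_len(d)])
}

#' Streamed (out-of-core) PCA
#'
#' Fits a PCA on streamed, standard-scaled blocks of normalised counts and
#' transforms every cell into the fitted space. Scaling statistics (mean, SD)
#' are fitted on the training cells only (`train_mask`); non-training cells
#' are transformed with the training scaler, mirroring train-on-a-subset
#' workflows. SDs below 1e-8 are clipped to 1.
#'
#' @param x an [AssayStore-class] or matrix of raw counts.
#' @param d number of components (must be < number of selected features).
#' @param feat_mask logical per feature; default all.
#' @param train_mask logical per cell used to fit scaler and components;
#'   default all cells.
#' @param block_fun optional `function(block, rows)` applied to each raw
#'   block before feature masking (e.g. library-size normalisation).
#' @param row_block rows per streamed block.
#' @param exact_threshold feature count up to which the covariance is
#'   eigendecomposed exactly; above it a seeded randomized subspace iteration
#'   is used.
#' @param seed seed for the randomized path.
#' @return a [ReducedMatrix-class] with coordinates for all cells.
#' @export
fitIncrementalPca <- function(x, d = 25L, feat_mask = NULL, train_mask = NULL,
                              block_fun = NULL, row_block = 2000L,
                              exact_threshold = 1000L, seed = 42L) {
  d <- .assertScalarCount(d, "d")
  n <- if (is(x, "AssayStore")) nCells(x) else nrow(x)
  p_all <- if (is(x, "AssayStore")) nFeatures(x) else ncol(x)
  feat_mask <- feat_mask %||% rep(TRUE, p_all)
  train_mask <- train_mask %||% rep(TRUE, n)
  p <- sum(feat_mask)
  if (d >= p) stop(sprintf("d (%d) must be smaller than the number of selected features (%d)",
                           d, p), call. = FALSE)
  if (!any(train_mask)) stop("train_mask selects no cells", call. = FALSE)
  block_fun <- block_fun %||% function(block, rows) block
  rb <- min(row_block, n)
  inMemory <- !is(x, "AssayStore")

  # pass 1: scaler on training cells; in-memory inputs keep the normalised
  # selected submatrix around so later passes are pure linear algebra
  Yfull <- NULL
  if (inMemory) {
    Yfull <- matrix(0, n, p)
  }
  s1 <- numeric(p); s2 <- numeric(p); ntr <- 0L
  streamBlocks(x, rb, function(block, rows) {
    y <- block_fun(block, rows)[, feat_mask, drop = FALSE]
    if (inMemory) Yfull[rows, ] <<- y
    tr <- train_mask[rows]
    if (any(tr)) {
      yt <- y[tr, , drop = FALSE]
      s1 <<- s1 + colSums(yt); s2 <<- s2 + colSums(yt^2); ntr <<- ntr + nrow(yt)
    }
    NULL
  })
  center <- s1 / ntr
  sdv <- sqrt(pmax(0, (s2 - ntr * center^2) / max(1, ntr - 1)))
  sdv[sdv < 1e-8] <- 1

  if (inMemory) {
    Z <- sweep(sweep(Yfull, 2, center), 2, sdv, `/`)
    Ztr <- Z[train_mask, , drop = FALSE]
    scaledTrainStream <- function(consume) {
      for (b in .rowBlocks(nrow(Ztr), rb)) consume(Ztr[b[1]:b[2], , drop = FALSE])
    }
  } else {
    scaledTrainStream <- function(consume) {
      streamBlocks(x, rb, function(block, rows) {
        tr <- train_mask[rows]
        if (any(tr)) {
          y <- block_fun(block, rows)[tr, feat_mask, drop = FALSE]
          consume(sweep(sweep(y, 2, center), 2, sdv, `/`))
        }
        NULL
      })
    }
  }
  eg <- .streamedTopEigen(scaledTrainStream, p, d, exact_threshold, seed)
  V <- eg$vectors

  # final pass transforms all cells
  if (inMemory) {
    coordsAll <- Z %*% V
  } else {
    coordsAll <- matrix(0, n, d)
    streamBlocks(x, rb, function(block, rows) {
      y <- block_fun(block, rows)[, feat_mask, drop = FALSE]
      z <- sweep(sweep(y, 2, center), 2, sdv, `/`)
      coordsAll[rows, ] <<- z %*% V
      NULL
    })
  }

  fids <- if (is(x, "AssayStore")) featureIds(x)[feat_mask] else
    (colnames(x) %||% sprintf("feat_%d", seq_len(p_all)))[feat_mask]
  new("ReducedMatrix", coords = coordsAll, method = "pca", d = d,
      center = center, scale = sdv, loadings = V, featureIds = fids)
}

#' Streamed LSI for TF-IDF-normalised peak matrices
#'
#' Latent semantic indexing: truncated SVD of the TF-IDF matrix, computed
#' without centering by streaming the Gram matrix (or a seeded randomized
#' sketch of it for wide matrices). The scATAC analogue of PCA.
#'
#' @param x an [AssayStore-class] or matrix of raw peak counts.
#' @param d number of components.
#' @param feat_mask logical per feature; default all.
#' @param stats global [tfidfStats()] of `x`; computed if missing.
#' @param row_block,exact_threshold,seed as in [fitIncrementalPca()].
#' @return a [ReducedMatrix-class] (`method = "lsi"`, no scaler).
#' @export
fitStreamingLsi <- function(x, d = 25L, feat_mask = NULL, stats = NULL,
                            row_block = 2000L, exact_threshold = 1000L,
                            seed = 42L) {
  d <- .assertScalarCount(d, "d")
  n <- if (is(x, "AssayStore")) nCells(x) else nrow(x)
  p_all <- if (is(x, "AssayStore")) nFeatures(x) else ncol(x)
  feat_mask <- feat_mask %||% rep(TRUE, p_all)
  p <- sum(feat_mask)
  if (d >= p) stop(sprintf("d (%d) must be smaller than the number of selected features (%d)",
                           d, p), call. = FALSE)
  stats <- stats %||% tfidfStats(x, row_block)
  rb <- min(row_block, n)

  tfidfStream <- function(consume) {
    streamBlocks(x, rb, function(block, rows) {
      consume(normalizeTfidf(block, stats, rows)[, feat_mask, drop = FALSE])
      NULL
    })
  }
  eg <- .streamedTopEigen(tfidfStream, p, d, exact_threshold, seed)
  V <- eg$vectors

  coordsAll <- matrix(0, n, d)
  streamBlocks(x, rb, function(block, rows) {
    y <- normalizeTfidf(block, stats, rows)[, feat_mask, drop = FALSE]
    coordsAll[rows, ] <<- y %*% V
    NULL
  })
  fids <- if (is(x, "AssayStore")) featureIds(x)[feat_mask] else
    (colnames(x) %||% sprintf("feat_%d", seq_len(p_all)))[feat_mask]
  new("ReducedMatrix", coords = coordsAll, method = "lsi", d = d,
      center = numeric(0), scale = numeric(0), loadings = V, featureIds = fids)
}

#' Transform new cells into a fitted reduced space
#'
#' Applies the training scaler (for PCA; LSI has none) and the fitted
#' loadings to a matrix whose columns are the reduction's features, in the
#' same order. The reduction is never refit.
#'
#' @param reduced a [ReducedMatrix-class].
#' @param x matrix of values over `reduced@featureIds` (cells x features).
#' @param apply_scaler apply the stored standard scaler before projecting
#'   (set `FALSE` when `x` is already in the scaled space, e.g. after CORAL).
#' @return cells x d coordinate matrix.
#' @export
transformCells <- function(reduced, x, apply_scaler = TRUE) {
  x <- .asDense(x)
  if (ncol(x) != nrow(reduced@loadings))
    stop(sprintf("x has %d features but the reduction was fitted on %d",
                 ncol(x), nrow(reduced@loadings)), call. = FALSE)
  if (apply_scaler && length(reduced@center)) {
    x <- sweep(sweep(x, 2, reduced@center), 2, reduced@scale, `/`)
  }
  x %*% reduced@loadings
}
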