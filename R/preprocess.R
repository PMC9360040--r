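# Cell filtering, count normalisation and feature selection.

#' Automatic two-sided cell filtering on a normal fit
#'
#' Fits a normal distribution to a chosen per-cell attribute (maximum
#' likelihood: sample mean and SD) and marks cells whose value falls below
#' the fitted quantile `x` or above the quantile `1 - x`.
#'
#' @param values numeric per-cell attribute (e.g. total counts); at least 3
#'   finite values required.
#' @param x tail probability in \[0, 0.5); default 0.01.
#' @return logical keep-mask, `TRUE` for cells that survive.
#' @examples
#' keep <- autoFilterCells(c(rnorm(100, 100, 10), 500), x = 0.01)
#' @export
autoFilterCells <- function(values, x = 0.01) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  if (sum(is.finite(values)) < 3) stop("need at least 3 finite values", call. = FALSE)
  if (x < 0 || x >= 0.5) stop("'x' must lie in [0, 0.5)", call. = FALSE)
  if (x == 0) return(rep(TRUE, length(values)))
  v <- values[is.finite(values)]
  m <- mean(v); s <- sd(v)
  if (!is.finite(s) || s == 0) {
    warning("zero variance in values; degenerate normal fit, keeping all cells")
    return(rep(TRUE, length(values)))
  }
  lo <- qnorm(x, m, s)
  hi <- qnorm(1 - x, m, s)
  is.finite(values) & values >= lo & values <= hi
}

#' Library-size normalisation of a block of counts
#'
#' Each cell's counts are scaled so its row sums to the scaling factor `S`:
#' `y = S * x / sum(x)`, optionally followed by `log(1 + y)` (natural log).
#'
#' @param block dense counts, cells x features; rownames (if any) are used in
#'   error messages.
#' @param S positive scaling factor, default 1000.
#' @param log_transform apply `log1p` after scaling.
#' @return normalised block of the same shape.
#' @export
normalizeLibrarySize <- function(block, S = 1000, log_transform = FALSE) {
  block <- .asDense(block)
  if (S <= 0) stop("'S' must be positive", call. = FALSE)
  rs <- rowSums(block)
  if (any(rs == 0)) {
    bad <- rownames(block)[rs == 0] %||% as.character(which(rs == 0))
    stop(sprintf("zero-sum cell(s): %s", paste(head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  out <- block * (S / rs)
  if (log_transform) out <- log1p(out)
  out
}

#' Global TF-IDF statistics of a count matrix
#'
#' The statistics feeding [normalizeTfidf()] must be computed over the full
#' matrix, never per chunk: `n_Fc` is the number of non-zero features
#' (accessible peaks) per cell, `n_Cf` the number of cells in which each
#' feature is non-zero, `N_C` the total cell count.
#'
#' @param x an [AssayStore-class] or matrix.
#' @param row_block rows per streamed block.
#' @return list with `n_Fc`, `n_Cf`, `N_C`.
#' @export
tfidfStats <- function(x, row_block = 2000L) {
  n <- if (is(x, "AssayStore")) nCells(x) else nrow(x)
  p <- if (is(x, "AssayStore")) nFeatures(x) else ncol(x)
  n_Fc <- numeric(n)
  n_Cf <- numeric(p)
  streamBlocks(x, min(row_block, n), function(block, rows) {
    nz <- block > 0
    n_Fc[rows] <<- rowSums(nz)
    n_Cf <<- n_Cf + colSums(nz)
    NULL
  })
  list(n_Fc = n_Fc, n_Cf = n_Cf, N_C = n)
}

#' TF-IDF normalisation of a block of peak counts
#'
#' `y = (x / n_Fc) * log(1 + N_C / n_Cf)` (natural log). Zeros stay zero;
#' features accessible in no cell contribute only zeros.
#'
#' @param block dense counts block, cells x features.
#' @param stats global statistics from [tfidfStats()].
#' @param rows row indices of `block` within the full matrix (for `n_Fc`);
#'   defaults to `1:nrow(block)`.
#' @return normalised block.
#' @export
normalizeTfidf <- function(block, stats, rows = seq_len(nrow(block))) {
  block <- .asDense(block)
  n_Fc <- stats$n_Fc[rows]
  if (any(n_Fc == 0)) {
    bad <- rownames(block)[n_Fc == 0] %||% as.character(rows[n_Fc == 0])
    stop(sprintf("cell(s) with no accessible features: %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  idf <- log(1 + stats$N_C / stats$n_Cf)
  idf[stats$n_Cf == 0] <- 0
  (block / n_Fc) * rep(idf, each = nrow(block))
}

# Default disqualification patterns: mitochondrial, ribosomal and a short
# cell-cycle list; matched case-insensitively against feature-id prefixes.
.defaultHvgBlocklist <- function() {
  list(prefixes = c("MT-", "RPS", "RPL", "MRPS", "MRPL"),
       genes = c("MKI67", "TOP2A", "CCNB1", "CCNB2", "CCNA2", "CCNE1",
                 "CDK1", "PCNA", "BIRC5", "AURKA", "AURKB"))
}

#' Trend-corrected highly variable gene selection
#'
#' Per-gene means and variances of the normalised values are log-transformed;
#' genes are divided into equal-count bins on log mean; from each bin one
#' anchor gene is taken (`bin_anchor = "lowest_variance"` by default, or the
#' literal `"lowest_mean"` reading); a lowess trend (span 0.4, 3 robustness
#' iterations) through the anchors predicts the expected log variance at each
#' gene's mean via linear interpolation, and `corrected = observed -
#' expected`. Mitochondrial/ribosomal/cell-cycle genes are disqualified
#' before selection. The top `n_top` eligible genes by corrected variance
#' (stable feature order on ties) are selected.
#'
#' @param means,variances per-gene mean and variance of normalised values
#'   (raw scale; log is taken internally).
#' @param feature_ids gene identifiers (for the disqualification patterns).
#' @param n_top number of genes to select.
#' @param n_bins number of equal-count bins (>= 2), default 20.
#' @param min_mean,max_mean optional constraints on log mean.
#' @param min_var optional lower bound on corrected log variance.
#' @param bin_anchor `"lowest_variance"` (default) or `"lowest_mean"`.
#' @param blocklist list with `prefixes` and `genes` (see source for default).
#' @return a data.frame with one row per gene: `id`, `mean`, `variance`
#'   (log scale), `expected_variance`, `corrected_variance`, `eligible`,
#'   `selected`.
#' @export
selectHvgs <- function(means, variances, feature_ids = NULL,
                       n_top = 2500L, n_bins = 20L,
                       min_mean = -Inf, max_mean = Inf, min_var = -Inf,
                       bin_anchor = c("lowest_variance", "lowest_mean"),
                       blocklist = .defaultHvgBlocklist()) {
  bin_anchor <- match.arg(bin_anchor)
  n_top <- .assertScalarCount(n_top, "n_top")
  n_bins <- .assertScalarCount(n_bins, "n_bins")
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  p <- length(means)
  if (length(variances) != p) stop("means and variances must have equal length", call. = FALSE)
  feature_ids <- feature_ids %||% sprintf("feat_%d", seq_len(p))

  expressed <- means > 0
  lm_ <- rep(NA_real_, p); lv <- rep(NA_real_, p)
  lm_[expressed] <- log(means[expressed])
  # variance can be 0 for constant expressed genes; floor keeps the log finite
  lv[expressed] <- log(pmax(variances[expressed], 1e-12))

  # equal-count bins on log mean (quantile bins; equal-width bins can be empty)
  idx <- which(expressed)
  qs <- quantile(lm_[idx], probs = seq(0, 1, length.out = n_bins + 1), names = FALSE)
  qs[1] <- qs[1] - 1e-9
  bins <- cut(lm_[idx], breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  anchors <- vapply(split(idx, bins), function(ii) {
    key <- if (bin_anchor == "lowest_variance") lv[ii] else lm_[ii]
    ii[which.min(key)]
  }, integer(1))

  fit <- lowess(lm_[anchors], lv[anchors], f = 0.4, iter = 3)
  expected <- rep(NA_real_, p)
  if (length(unique(fit$x)) >= 2) {
    expected[idx] <- approx(fit$x, fit$y, xout = lm_[idx], rule = 2, ties = mean)$y
  } else {
    expected[idx] <- fit$y[1]
  }
  corrected <- lv - expected

  blocked <- rep(FALSE, p)
  if (length(blocklist$prefixes))
    blocked <- blocked | Reduce(`|`, lapply(blocklist$prefixes, function(pre)
      startsWith(toupper(feature_ids), toupper(pre))))
  if (length(blocklist$genes))
    blocked <- blocked | toupper(feature_ids) %in% toupper(blocklist$genes)

  eligible <- expressed & !blocked &
    !is.na(lm_) & lm_ >= min_mean & lm_ <= max_mean &
    !is.na(corrected) & corrected >= min_var
  n_eligible <- sum(eligible)
  if (n_top > n_eligible) {
    warning(sprintf("n_top (%d) exceeds eligible genes (%d); selecting all eligible",
                    n_top, n_eligible))
    n_top <- n_eligible
  }
  selected <- rep(FALSE, p)
  if (n_top > 0) {
    ord <- order(-corrected[eligible], seq_len(p)[eligible])
    selected[which(eligible)[ord[seq_len(n_top)]]] <- TRUE
  }
  data.frame(id = feature_ids, mean = lm_, variance = lv,
             expected_variance = expected, corrected_variance = corrected,
             eligible = eligible, selected = selected,
             stringsAsFactors = FALSE)
}

#' Per-gene means and variances of normalised values, streamed
#'
#' Streams library-size-normalised blocks and accumulates per-gene mean and
#' variance (denominator n - 1) for [selectHvgs()].
#'
#' @param x an [AssayStore-class] or matrix of raw counts.
#' @param S,log_transform passed to [normalizeLibrarySize()].
#' @param row_block rows per streamed block.
#' @return list with `means` and `variances` per gene (raw scale).
#' @export
geneStats <- function(x, S = 1000, log_transform = TRUE, row_block = 2000L) {
  n <- if (is(x, "AssayStore")) nCells(x) else nrow(x)
  p <- if (is(x, "AssayStore")) nFeatures(x) else ncol(x)
  s1 <- numeric(p); s2 <- numeric(p)
  streamBlocks(x, min(row_block, n), function(block, rows) {
    y <- normalizeLibrarySize(block, S = S, log_transform = log_transform)
    s1 <<- s1 + colSums(y)
    s2 <<- s2 + colSums(y^2)
    NULL
  })
  mu <- s1 / n
  list(means = mu, variances = pmax(0, (s2 - n * mu^2) / (n - 1)))
}

#' Peak prevalence scores and top-peak selection
#'
#' The prevalence score of a peak is the column sum of the TF-IDF normalised
#' matrix; `selectTopPeaks()` marks the top `n` peaks by prevalence (ties
#' broken by stable feature order).
#'
#' @param x an [AssayStore-class] or matrix of peak counts.
#' @param stats global [tfidfStats()]; computed from `x` if missing.
#' @param row_block rows per streamed block.
#' @return `peakPrevalence()`: numeric per-feature prevalence.
#' @export
peakPrevalence <- function(x, stats = NULL, row_block = 2000L) {
  stats <- stats %||% tfidfStats(x, row_block)
  n <- if (is(x, "AssayStore")) nCells(x) else nrow(x)
  prev <- numeric(length(stats$n_Cf))
  streamBlocks(x, min(row_block, n), function(block, rows) {
    prev <<- prev + colSums(normalizeTfidf(block, stats, rows))
    NULL
  })
  prev
}

#' @rdname peakPrevalence
#' @param scores per-feature prevalence scores.
#' @param n number of peaks to keep.
#' @return `selectTopPeaks()`: logical mask with exactly `n` `TRUE`.
#' @export
selectTopPeaks <- function(scores, n) {
  n <- .assertScalarCount(n, "n")
  if (n > length(scores)) stop("'n' exceeds the number of features", call. = FALSE)
  mask <- rep(FALSE, length(scores))
  mask[order(-scores, seq_along(scores))[seq_len(n)]] <- TRUE
  mask
}
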