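test_that("auto cell filter matches normal-quantile cutoffs and handles degenerate fits", {
  set.seed(1)
  v <- rnorm(5000, 100, 10)
  keep <- autoFilterCells(v, x = 0.01)
  # oracle: the fitted-normal quantiles 100 +/- 2.326 * 10 (sample estimates)
  lo <- qnorm(0.01, mean(v), sd(v)); hi <- qnorm(0.99, mean(v), sd(v))
  expect_equal(keep, v >= lo & v <= hi)
  expect_equal(lo, mean(v) + qnorm(0.01) * sd(v), tolerance = 1e-12)
  expect_true(all(autoFilterCells(v, x = 0)))
  expect_warning(k2 <- autoFilterCells(rep(5, 10), x = 0.1), "zero variance")
  expect_true(all(k2))
  expect_error(autoFilterCells(c(1, 2), x = 0.1), "at least 3")
  expect_error(autoFilterCells(v, x = 0.5), "0.5")
})

test_that("library-size normalisation scales every cell to S", {
  expect_equal(normalizeLibrarySize(matrix(c(2, 3, 5), 1, 3), S = 1000)[1, ],
               c(200, 300, 500))
  set.seed(2)
  m <- matrix(rpois(40 * 10, 3) + 1, 40, 10)
  y <- normalizeLibrarySize(m, S = 1000)
  expect_lt(max(abs(rowSums(y) - 1000)), 1e-9)
  ylog <- normalizeLibrarySize(m, S = 1000, log_transform = TRUE)
  expect_equal(ylog, log1p(y))
  expect_equal(ylog[m == 0], rep(0, sum(m == 0)))   # ln(1+0) preserved
  bad <- rbind(m, 0)
  rownames(bad) <- sprintf("c%d", seq_len(nrow(bad)))
  expect_error(normalizeLibrarySize(bad), "c41")
})

test_that("TF-IDF normalisation matches hand-computed values and keeps zeros", {
  x <- matrix(c(1, 1, 0, 1), 2, 2)   # cells x peaks: cell1=(1,0), cell2=(1,1)
  st <- tfidfStats(x)
  expect_equal(st$n_Fc, c(1, 2))
  expect_equal(st$n_Cf, c(2, 1))
  y <- normalizeTfidf(x, st)
  expect_equal(y[1, 1], log(2))
  expect_equal(y[2, 2], log(3) / 2)
  expect_equal(y[2, 1], log(2) / 2)
  expect_equal(y[1, 2], 0)
  allz <- rbind(x, c(0, 0))
  expect_error(normalizeTfidf(allz, tfidfStats(allz)), "no accessible")
})

test_that("TF-IDF via chunks equals TF-IDF of the full matrix (global stats)", {
  set.seed(3)
  m <- matrix(rbinom(60 * 25, 3, 0.2), 60, 25)
  m[rowSums(m) == 0, 1] <- 1
  st <- tfidfStats(m)
  full <- normalizeTfidf(m, st)
  for (rb in c(1, 7, 60)) {
    got <- do.call(rbind, streamBlocks(m, rb, function(block, rows)
      normalizeTfidf(block, st, rows)))
    expect_lt(max(abs(got - full)), 1e-10)
  }
})

test_that("HVG selection ranks trend-corrected variance and honours constraints", {
  set.seed(4)
  p <- 200
  means <- rexp(p) + 0.1
  variances <- means * (1 + rexp(p, 5))
  ids <- sprintf("G%03d", seq_len(p))
  sel <- selectHvgs(means, variances, ids, n_top = 40, n_bins = 10)
  expect_equal(sum(sel$selected), 40)
  expect_equal(sel$corrected_variance, sel$variance - sel$expected_variance)
  # a gene with inflated variance at equal mean must outrank its peer
  v2 <- variances
  peers <- order(means)[100:101]
  v2[peers[1]] <- v2[peers[2]] * 4
  sel2 <- selectHvgs(means, v2, ids, n_top = 40, n_bins = 10)
  r <- rank(-sel2$corrected_variance)
  expect_lt(r[peers[1]], r[peers[2]])
  # monotonicity: raising a gene's variance never lowers its rank
  sel3 <- selectHvgs(means, v2 + (seq_len(p) == peers[1]) * 5, ids, n_top = 40, n_bins = 10)
  expect_lte(rank(-sel3$corrected_variance)[peers[1]], r[peers[1]])
  # mean constraint excludes genes outright
  selc <- selectHvgs(means, variances, ids, n_top = 40, n_bins = 10,
                     min_mean = log(0.5))
  expect_true(all(selc$mean[selc$selected] >= log(0.5)))
  expect_warning(selAll <- selectHvgs(means, variances, ids, n_top = 1000),
                 "exceeds eligible")
  expect_equal(sum(selAll$selected), sum(selAll$eligible))
})

test_that("ties in corrected variance resolve in stable feature order", {
  p <- 30
  sel <- selectHvgs(rep(2, p), rep(3, p), n_top = 5, n_bins = 2)
  expect_equal(which(sel$selected), 1:5)
})

test_that("blocklisted gene families are disqualified from HVG selection", {
  ids <- c("MT-CO1", "RPS4", "RPL3", "MKI67", sprintf("G%d", 1:46))
  set.seed(5)
  means <- rexp(50) + 0.5
  variances <- means * 2
  variances[1:4] <- variances[1:4] * 100   # would otherwise dominate
  sel <- selectHvgs(means, variances, ids, n_top = 10, n_bins = 5)
  expect_false(any(sel$selected[1:4]))
  expect_false(any(sel$eligible[1:4]))
})

test_that("peak prevalence is the TF-IDF column sum and top-n selection is stable", {
  x <- matrix(c(1, 1, 0, 1), 2, 2)
  prev <- peakPrevalence(x)
  expect_equal(prev, c(1.5 * log(2), log(3) / 2))
  expect_equal(selectTopPeaks(prev, 1), c(TRUE, FALSE))
  expect_equal(selectTopPeaks(prev, 2), c(TRUE, TRUE))
  set.seed(6)
  m <- cbind(0, matrix(rbinom(30 * 5, 2, 0.4), 30, 5))
  m[rowSums(m) == 0, 2] <- 1
  pv <- peakPrevalence(m)
  expect_equal(pv[1], 0)
  expect_false(selectTopPeaks(pv, 5)[1])    # all-zero peak never in top-n
  expect_error(selectTopPeaks(pv, 0), "positive")
})

test_that("gene statistics and normalisation are chunk-size independent", {
  set.seed(7)
  m <- matrix(rpois(53 * 12, 2) + 1, 53, 12)
  ref <- geneStats(m, row_block = 53)
  for (rb in c(1, 7)) {
    gs <- geneStats(m, row_block = rb)
    expect_lt(max(abs(gs$means - ref$means)), 1e-10)
    expect_lt(max(abs(gs$variances - ref$variances)), 1e-10)
  }
})
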