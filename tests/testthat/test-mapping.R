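test_that("common-total rescaling hits the target sum and excludes zero-HVG cells", {
  expect_equal(rescaleToCommonTotal(matrix(c(2, 3, 5), 1, 3))[1, ],
               c(200, 300, 500))
  set.seed(1)
  m <- matrix(rpois(40 * 20, 2), 40, 20) + 1
  hvg <- seq_len(20) <= 8
  r <- rescaleToCommonTotal(m, hvg)
  expect_equal(ncol(r), 8)
  expect_lt(max(abs(rowSums(r) - 1000)), 1e-9)
  # idempotence: a row already summing to the total is unchanged
  again <- rescaleToCommonTotal(r)
  expect_lt(max(abs(again - r)), 1e-9)
  z <- m; z[5, hvg] <- 0
  rownames(z) <- sprintf("c%d", 1:40)
  expect_warning(rz <- rescaleToCommonTotal(z, hvg), "c5")
  expect_equal(nrow(rz), 39)
  expect_equal(attr(rz, "excluded"), "c5")
})

test_that("CORAL makes the corrected target covariance match the reference", {
  set.seed(2)
  n <- 4000; p <- 12
  L <- matrix(rnorm(p * p, sd = 0.4), p, p); diag(L) <- 1
  S <- matrix(rnorm(n * p), n, p) %*% L
  T_ <- matrix(rnorm(n * p), n, p) %*% L
  T_dist <- sweep(T_, 2, seq(0.5, 3, length.out = p), `*`)   # per-feature scale shift
  cc <- coralCorrect(S, T_dist, shrinkage = 1)
  relerr <- norm(cov(cc$T_corrected) - cov(cc$S_scaled), "F") /
    norm(cov(cc$S_scaled), "F")
  expect_lt(relerr, 0.05)
  fv <- apply(cc$T_corrected, 2, var) / apply(cc$S_scaled, 2, var)
  expect_true(all(abs(fv - 1) < 0.05))   # per-feature variances within 5%
  # exactly-identity covariances: A = I and the target passes through unchanged
  whiten <- function(m) m %*% solve(chol(cov(m)))
  S0 <- whiten(matrix(rnorm(n * p), n, p))
  T0 <- whiten(matrix(rnorm(n * p), n, p))
  cc0 <- coralCorrect(S0, T0)
  zT0 <- sweep(sweep(T0, 2, colMeans(T0)), 2, apply(T0, 2, sd), `/`)
  expect_lt(max(abs(cc0$A - diag(p))), 1e-8)
  expect_lt(max(abs(cc0$T_corrected - zT0)), 1e-8)
  # T = S maps onto itself
  ccS <- coralCorrect(S, S)
  expect_lt(max(abs(ccS$T_corrected - ccS$S_scaled)), 1e-6)
  colnames(S) <- sprintf("g%d", 1:p)
  T2 <- T_; colnames(T2) <- c(sprintf("g%d", 2:p), "g_other")
  expect_error(coralCorrect(S, T2), "HVG mismatch")
})

test_that("mapping weights follow W = 1/(ln(D+1)+1) with W(0) = 1", {
  ref <- matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE)
  idx <- buildKnnIndex(ref)
  mp <- mapCells(idx, matrix(c(0, 0), 1, 2), k = 2)
  expect_equal(edgeWeights(mp)[1, 1], 1)
  expect_equal(knnDistances(mp)[1, ], c(0, 3))
  expect_equal(edgeWeights(mp)[1, 2], 1 / (log(4) + 1))
  mp2 <- mapCells(idx, matrix(c(0, exp(1) - 1), 1, 2), k = 1)
  expect_equal(edgeWeights(mp2)[1, 1], 0.5)    # D = e - 1 inverts to W = 1/2
  d <- seq(0, 10, by = 0.5)
  expect_true(all(diff(1 / (log(d + 1) + 1)) < 0))
  expect_error(mapCells(idx, matrix(0, 1, 3), k = 1), "dimensionality")
})

test_that("unified graph spikes targets with top_m unit edges without touching the reference", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30, 4)
  g <- smoothEdgeWeights(buildKnnGraph(X, k = 5))
  refAdj <- symmetrizedAdjacency(g)
  idx <- buildKnnIndex(X)
  mp <- mapCells(idx, X[1:2, ] + 0.01, k = 5)
  U <- unifiedGraph(g, mp, top_m = 3, spike_weight = 1)
  expect_equal(dim(U), c(32, 32))
  expect_equal(as.matrix(U[1:30, 1:30]), as.matrix(refAdj))  # non-interference
  expect_equal(Matrix::rowSums(U[31:32, ] > 0), c(3, 3), ignore_attr = TRUE)
  expect_true(all(U[31, U[31, ] > 0] == 1))
  mp0 <- mapCells(idx, X[integer(0), , drop = FALSE], k = 5)
  expect_equal(as.matrix(unifiedGraph(g, mp0)), as.matrix(refAdj))
  expect_error(unifiedGraph(g, mp, top_m = 6), "exceeds")
})

test_that("mapping scores aggregate per reference and scale inversely with N_T", {
  ref <- matrix(c(0, 0, 5, 0, 0, 5), 3, 2, byrow = TRUE)
  idx <- buildKnnIndex(ref)
  mp1 <- mapCells(idx, matrix(c(0, 0), 1, 2), k = 1)
  M1 <- mappingScores(mp1)
  expect_equal(M1[1], 1)               # single target at D = 0, N_T = 1
  expect_equal(M1[2], 0)               # unmapped reference
  mp2 <- mapCells(idx, matrix(c(0, 0, 0, 0), 2, 2, byrow = TRUE), k = 1)
  expect_equal(mappingScores(mp2), M1) # same hits, doubled N_T, doubled mass
  mp3 <- mapCells(idx, rbind(c(0, 0), c(5, 0)), k = 1)
  expect_equal(mappingScores(mp3), c(0.5, 0.5, 0))
  Ml <- mappingScores(mp3, multiplier = 1000, log_transform = TRUE)
  expect_equal(Ml[1], log(501))
})

test_that("label transfer follows the 50% unique-majority rule", {
  w <- matrix(c(0.6, 0.4), 1, 2)
  mk <- function(w, idx, labs) {
    mp <- new("MappingResult", knnIdx = idx, knnDist = 0 * idx,
              weights = w, nRef = max(idx), k = ncol(idx),
              targetIds = character(0))
    transferLabels(mp, labs)
  }
  expect_equal(mk(matrix(c(0.6, 0.4), 1), matrix(c(1L, 2L), 1), c("A", "B")), "A")
  expect_equal(mk(matrix(c(0.4, 0.4, 0.2), 1), matrix(c(1L, 2L, 3L), 1),
                  c("A", "B", "C")), NA_character_)
  expect_equal(mk(matrix(c(0.5, 0.5), 1), matrix(c(1L, 2L), 1), c("A", "B")),
               NA_character_)                     # exact tie forces NA
  expect_equal(mk(matrix(c(0.3, 0.3, 0.4), 1), matrix(c(1L, 2L, 3L), 1),
                  c("A", "A", "B")), "A")         # summed per class: A = 0.6
})

test_that("self-mapping transfers every label and CORAL recovers a distorted batch", {
  sim <- makeClusteredCounts(n_cells = 800, n_genes = 500,
                             cluster_props = c(0.4, 0.35, 0.25),
                             de_fraction = 0.2, fold = 6, seed = 5)
  ref <- suppressWarnings(fitReferenceModel(sim$counts, n_hvgs = 150, dims = 10,
                                            k = 11, seed = 1))
  self <- suppressWarnings(mapTargetCounts(ref, sim$counts, k = 1, coral = FALSE))
  tl <- transferLabels(self$mapping, as.character(sim$labels))
  expect_equal(mean(tl == as.character(sim$labels)), 1)
  expect_lt(max(knnDistances(self$mapping)), 1e-5)
  # distorted second batch (same populations): CORAL accuracy dominates
  sim2 <- makeClusteredCounts(n_cells = 1600, n_genes = 500,
                              cluster_props = c(0.4, 0.35, 0.25),
                              de_fraction = 0.2, fold = 6, seed = 5)
  set.seed(6)
  refIdx <- sort(sample(1600, 800)); tarIdx <- setdiff(1:1600, refIdx)
  ref2 <- suppressWarnings(fitReferenceModel(sim2$counts[refIdx, ], n_hvgs = 150,
                                             dims = 10, k = 11, seed = 1))
  set.seed(7); scl <- rlnorm(500, 0, 1)
  tar <- sweep(sim2$counts[tarIdx, ], 2, scl, `*`)
  withC <- suppressWarnings(mapTargetCounts(ref2, tar, k = 11, coral = TRUE))
  noC <- suppressWarnings(mapTargetCounts(ref2, tar, k = 11, coral = FALSE))
  truth <- as.character(sim2$labels[tarIdx])
  refLabs <- as.character(sim2$labels[refIdx])
  accW <- mean(transferLabels(withC$mapping, refLabs) == truth)
  accN <- mean(transferLabels(noC$mapping, refLabs) == truth, na.rm = TRUE)
  expect_gte(accW, 0.95)
  expect_lte(accN, accW + 1e-12)
})
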