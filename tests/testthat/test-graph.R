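test_that("exact KNN graph equals brute-force search with recall 1", {
  set.seed(1)
  X <- matrix(rnorm(80 * 4), 80, 4)
  g <- buildKnnGraph(X, k = 5)
  D <- as.matrix(dist(X))
  bf <- t(apply(D, 1, function(r) order(r)[2:6]))
  expect_equal(unname(knnIndices(g)), unname(bf))
  expect_equal(recallValue(g), 1)
  expect_true(all(knnIndices(g) != seq_len(80)))
  expect_true(all(diff(t(knnDistances(g))) > -1e-12))
  expect_error(buildKnnGraph(X, k = 80), "smaller")
})

test_that("2D grid neighbourhoods match Euclidean geometry", {
  pts <- as.matrix(expand.grid(x = 1:6, y = 1:6))
  g <- buildKnnGraph(pts, k = 4)
  # interior points neighbour exactly their 4 axis neighbours
  interior <- which(pts[, 1] %in% 2:5 & pts[, 2] %in% 2:5)
  for (i in interior) {
    expected <- which(abs(pts[, 1] - pts[i, 1]) + abs(pts[, 2] - pts[i, 2]) == 1)
    expect_setequal(knnIndices(g)[i, ], expected)
  }
})

test_that("duplicated cells list each other at distance zero", {
  set.seed(2)
  X <- matrix(rnorm(20 * 3), 20, 3)
  X[7, ] <- X[3, ]
  g <- buildKnnGraph(X, k = 4)
  expect_equal(knnIndices(g)[3, 1], 7)
  expect_equal(knnIndices(g)[7, 1], 3)
  expect_equal(knnDistances(g)[3, 1], 0)
})

test_that("graph construction is reproducible and the index round-trips disk", {
  set.seed(3)
  X <- matrix(rnorm(50 * 5), 50, 5)
  f <- tempfile()
  g1 <- buildKnnGraph(X, k = 6, seed = 9, index_path = f)
  g2 <- buildKnnGraph(X, k = 6, seed = 9)
  expect_identical(knnIndices(g1), knnIndices(g2))
  idx <- loadKnnIndex(f)
  res <- queryKnnIndex(idx, X[1:3, , drop = FALSE], 6)
  expect_equal(res$idx[, 1], 1:3)   # saved index answers self-queries
})

test_that("edge-weight smoothing hits the log2(k) budget with weight 1 at rho", {
  set.seed(4)
  X <- matrix(rnorm(100 * 6), 100, 6)
  g <- smoothEdgeWeights(buildKnnGraph(X, k = 8))
  w <- edgeWeights(g)
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(w[, 1] == 1))
  expect_lt(max(abs(rowSums(w) - log2(8))), 1e-3)
  # hand case: distances [1, 2] at k = 2 force sigma to the clamp: weights ~ [1, 0]
  gg <- new("NeighbourGraph", knnIdx = matrix(c(2L, 1L, 3L, 3L), 2, 2),
            knnDist = matrix(c(1, 1, 2, 2), 2, 2), weights = matrix(0, 0, 0),
            k = 2L, recall = 1, backend = "exact")
  ws <- edgeWeights(smoothEdgeWeights(gg))
  expect_equal(ws[1, 1], 1)
  expect_lt(ws[1, 2], 1e-6)
  # all-equal distances clamp to all-1 weights
  ge <- new("NeighbourGraph", knnIdx = matrix(c(2L, 1L, 3L, 3L), 2, 2),
            knnDist = matrix(1, 2, 2), weights = matrix(0, 0, 0),
            k = 2L, recall = 1, backend = "exact")
  expect_true(all(edgeWeights(smoothEdgeWeights(ge)) == 1))
})

test_that("symmetrized adjacency applies the fuzzy union to reciprocated edges", {
  # 3 colinear points: 1-2 reciprocal at k=1; 2-3 one-sided is kept
  X <- matrix(c(0, 1, 3), 3, 1)
  g <- smoothEdgeWeights(buildKnnGraph(X, k = 1))
  w <- edgeWeights(g)
  A <- symmetrizedAdjacency(g)
  expect_true(Matrix::isSymmetric(A))
  expect_equal(A[1, 2], w[1, 1] + w[2, 1] - w[1, 1] * w[2, 1])
  expect_equal(A[2, 3], w[3, 1])
  expect_equal(A[1, 3], 0)
  expect_true(all(Matrix::diag(A) == 0))
})

test_that("initial embedding assigns shared centroid coordinates per k-means cluster", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60 * 3, 0, 0.01), 60, 3),
             matrix(rnorm(40 * 3, 10, 0.01), 40, 3))
  ie <- initialEmbedding(X, c = 2, dim = 2, seed = 1)
  expect_equal(nrow(unique(round(ie$coords, 6))), 2)
  expect_equal(length(unique(ie$cluster_of_cell[1:60])), 1)
  same <- ie$cluster_of_cell == ie$cluster_of_cell[1]
  expect_true(all(ie$coords[same, 1] == ie$coords[1, 1]))
  ie2 <- initialEmbedding(X, c = 2, dim = 2, seed = 1)
  expect_identical(ie$coords, ie2$coords)
  expect_error(initialEmbedding(X, c = 101, dim = 2), "n_cells")
  # c = n distinct points: init coords reproduce the dim-leading PCA up to sign
  set.seed(6)
  Y <- matrix(rnorm(20 * 4), 20, 4)
  ie3 <- initialEmbedding(Y, c = 20, dim = 2, seed = 1)
  pc <- prcomp(Y)$x[, 1:2]
  ord <- order(ie3$cluster_of_cell)
  relerr <- min(norm(ie3$coords - pc, "F"), norm(ie3$coords + pc, "F"),
                norm(sweep(ie3$coords, 2, c(1, -1), `*`) - pc, "F"),
                norm(sweep(ie3$coords, 2, c(-1, 1), `*`) - pc, "F")) / norm(pc, "F")
  expect_lt(relerr, 1e-6)
})

test_that("hnsw backend requests fail loudly when the engine is missing", {
  X <- matrix(rnorm(30), 10, 3)
  if (requireNamespace("RcppHNSW", quietly = TRUE)) {
    g <- buildKnnGraph(X, k = 3, backend = "hnsw")
    expect_gte(recallValue(g), 0.9)
  } else {
    expect_error(buildKnnGraph(X, k = 3, backend = "hnsw"), "RcppHNSW")
  }
})
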