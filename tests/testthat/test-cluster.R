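test_that("Leiden recovers planted cliques and matches the modularity bipartition oracle", {
  adj <- makeToyGraph("two_cliques_bridge", c(5, 5))
  oracle <- bestBipartitionModularity(adj)
  expect_equal(oracle$partition, rep(1:2, each = 5))   # brute force over bipartitions
  lab <- leidenCluster(adj, seed = 1)
  expect_equal(ari(lab, oracle$partition), 1)
  big <- makeToyGraph("two_cliques_bridge", c(10, 10))
  lab10 <- leidenCluster(big, seed = 1)
  expect_equal(ari(lab10, rep(1:2, each = 10)), 1)
  # complete graph collapses to one cluster at low resolution
  expect_equal(unique(leidenCluster(makeToyGraph("clique", 8), resolution = 0.1,
                                    seed = 1)), 1L)
  expect_identical(leidenCluster(big, seed = 7), leidenCluster(big, seed = 7))
  expect_error(leidenCluster(Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                                  dims = c(3, 3),
                                                  symmetric = TRUE)), "no edges")
})

test_that("labels are contiguous and size-ordered", {
  adj <- makeToyGraph("two_cliques_bridge", c(8, 4))
  lab <- leidenCluster(adj, seed = 1)
  expect_equal(sort(unique(lab)), seq_len(max(lab)))
  sizes <- as.vector(table(lab))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(lab[1], 1L)   # the larger clique is cluster 1
})

test_that("Paris NN-chain equals exhaustive greedy agglomeration on enumerated graphs", {
  set.seed(1)
  for (n in 2:5) {
    graphs <- allConnectedGraphs(n)
    pick <- if (length(graphs) > 120) sample(graphs, 120) else graphs
    for (e in pick) {
      w <- runif(nrow(e), 0.2, 1)
      adj <- edgesToAdjacency(e, n, w)
      got <- parisDendrogram(adj)@heights
      oracle <- parisGreedyOracle(adj)
      expect_equal(sort(got[is.finite(got)]), sort(oracle), tolerance = 1e-9)
    }
  }
  # random larger graphs
  for (n in 6:8) {
    for (rep in 1:15) {
      e <- randomConnectedGraph(n)
      adj <- edgesToAdjacency(e, n, runif(nrow(e), 0.2, 1))
      got <- parisDendrogram(adj)@heights
      expect_equal(sort(got), sort(parisGreedyOracle(adj)), tolerance = 1e-9)
    }
  }
})

test_that("Paris dendrogram structure: n-1 merges, clique split, heavy edge first", {
  adj <- makeToyGraph("two_cliques_bridge", c(5, 5))
  dend <- parisDendrogram(adj)
  expect_equal(nrow(dend@merges), 9)
  expect_equal(cutDendrogram(dend, 2), rep(1:2, each = 5))   # topmost merge = bridge
  # weighted triangle: the heavy pair merges first
  tri <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(2, 3, 3), x = c(10, 1, 1),
                              dims = c(3, 3), symmetric = TRUE)
  d3 <- parisDendrogram(tri)
  expect_equal(sort(d3@merges[1, ]), c(1, 2))
  expect_error(parisDendrogram(Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                                    dims = c(2, 2),
                                                    symmetric = TRUE)), "zero edges")
})

test_that("disconnected components join under an infinite root and split first", {
  two <- edgesToAdjacency(rbind(c(1, 2), c(3, 4)), 4)
  dend <- parisDendrogram(two)
  expect_equal(nrow(dend@merges), 3)
  expect_true(is.infinite(dend@heights[3]))
  expect_equal(ari(cutDendrogram(dend, 2), c(1, 1, 2, 2)), 1)
})

test_that("dendrogram cuts are nested partitions from k = 1 to n", {
  set.seed(2)
  e <- randomConnectedGraph(12, extra = 10)
  adj <- edgesToAdjacency(e, 12, runif(nrow(e), 0.1, 1))
  dend <- parisDendrogram(adj)
  expect_equal(unique(cutDendrogram(dend, 1)), 1L)
  expect_equal(sort(cutDendrogram(dend, 12)), 1:12)
  prev <- cutDendrogram(dend, 1)
  for (k in 2:12) {
    cur <- cutDendrogram(dend, k)
    expect_equal(length(unique(cur)), k)
    # refinement: cells sharing a cluster at k share one at k-1
    expect_true(all(tapply(prev, cur, function(v) length(unique(v))) == 1))
    prev <- cur
  }
  expect_error(cutDendrogram(dend, 13), "exceeds")
})

test_that("cluster similarity sums edge weights within and between clusters", {
  p <- makeToyGraph("path", 3)
  expect_equal(clusterSimilarityGraph(p, c(1, 2, 2)),
               matrix(c(0, 1, 1, 1), 2, 2))
  clq <- makeToyGraph("clique", 4, weight = 0.5)
  expect_equal(clusterSimilarityGraph(clq, rep(1, 4)),
               matrix(3, 1, 1))                      # conservation: total edge weight
  two <- edgesToAdjacency(rbind(c(1, 2), c(3, 4)), 4)
  expect_equal(clusterSimilarityGraph(two, c(1, 1, 2, 2)),
               matrix(c(1, 0, 0, 1), 2, 2))
  expect_error(clusterSimilarityGraph(p, c(1, 2)), "length")
})

test_that("Newick export and hclust conversion preserve the tree", {
  adj <- makeToyGraph("two_cliques_bridge", c(3, 3))
  dend <- parisDendrogram(adj)
  nwk <- exportNewick(dend)
  expect_match(nwk, "^\\(.*\\);$")
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), sort(sprintf("cell_%d", 1:6)))
  hc <- as.hclust(dend)
  expect_s3_class(hc, "hclust")
  expect_equal(ari(cutree(hc, 2), rep(1:2, each = 3)), 1)
})

test_that("embedding engines honour the identity, determinism and finiteness contract", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40 * 3, 0, 0.3), 40, 3), matrix(rnorm(40 * 3, 8, 0.3), 40, 3))
  g <- smoothEdgeWeights(buildKnnGraph(X, k = 6))
  ie <- initialEmbedding(X, c = 4, dim = 2, seed = 1)
  expect_identical(embedCells(g, ie, engine = "fr", n_iter = 0), ie$coords)
  e1 <- embedCells(g, ie, engine = "fr", n_iter = 100, seed = 5)
  e2 <- embedCells(g, ie, engine = "fr", n_iter = 100, seed = 5)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  # far-separated clusters stay separated: centroid gap > intra-cluster spread
  lab <- rep(1:2, each = 40)
  cent <- rowsum(e1, lab) / 40
  gap <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  intra <- mean(sqrt(rowSums((e1 - cent[lab, ])^2)))
  expect_gt(gap, intra)
  expect_error(embedCells(g, ie, engine = "graph-tsne", n_iter = 10),
               "not available")
})
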