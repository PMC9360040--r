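test_that("neighbourhood degree matches hand counts on stars and regular graphs", {
  s <- makeToyGraph("star", 3)
  expect_equal(neighbourhoodDegree(s, 1), c(3, 3, 3, 3))
  r <- makeToyGraph("clique", 5)           # 4-regular
  expect_equal(neighbourhoodDegree(r, 1), rep(16, 5))
  iso <- edgesToAdjacency(rbind(c(1, 2)), 3)
  expect_equal(neighbourhoodDegree(iso, 1)[3], 0)
  expect_equal(neighbourhoodDegree(iso, 2)[3], 0)
  # path 1-2-3: 2-step neighbourhood of node 1 covers nodes 2 and 3
  p <- makeToyGraph("path", 3)
  expect_equal(neighbourhoodDegree(p, 1), c(2, 2, 2))
  expect_equal(neighbourhoodDegree(p, 2), c(3, 2, 3))
  expect_error(neighbourhoodDegree(p, 0), "positive")
})

test_that("neighbourhood connectedness matches hand-computed Jaccard sums", {
  expect_equal(neighbourhoodConnectedness(makeToyGraph("clique", 3)),
               rep(2 / 3, 3))
  expect_equal(neighbourhoodConnectedness(makeToyGraph("clique", 4)),
               rep(1.5, 4))
  expect_equal(neighbourhoodConnectedness(makeToyGraph("star", 3)),
               rep(0, 4))
  iso <- edgesToAdjacency(rbind(c(1, 2)), 3)
  expect_equal(neighbourhoodConnectedness(iso)[3], 0)
})

test_that("sampling rates are monotone in topology and capped", {
  labels <- rep(1:3, each = 100)
  topo <- list(nnd = c(rep(10, 100), rep(20, 100), rep(40, 100)),
               nc = c(rep(1, 100), rep(2, 100), rep(4, 100)))
  plan <- samplingPlan(labels, topo, base_rate = 0.1)
  expect_true(all(diff(plan$rate) <= 0))     # denser clusters sampled less
  expect_true(all(plan$rate <= 0.1 + 1e-12))
  expect_true(all(plan$n_to_sample >= 1))
  flat <- samplingPlan(labels, list(nnd = rep(5, 300), nc = rep(1, 300)),
                       base_rate = 0.01)
  expect_equal(flat$rate, rep(0.01, 3))      # identical topology, equal rates
  expect_equal(flat$n_to_sample, rep(1L, 3))
  expect_error(samplingPlan(labels, topo, base_rate = 0.1, max_rate = 1.5), "max_rate")
})

test_that("seed selection takes one medoid per sub-cluster, deterministically", {
  set.seed(1)
  X <- rbind(matrix(rnorm(30 * 2, 0, 0.1), 30, 2),
             matrix(rnorm(30 * 2, 5, 0.1), 30, 2))
  labels <- rep(1L, 60)                      # one cluster, two spatial blobs
  plan <- data.frame(cluster = 1L, size = 60L, median_nnd = 0, median_nc = 0,
                     rate = 0.03, n_to_sample = 2L)
  seeds <- selectSeeds(X, labels, plan, seed = 2)
  expect_length(seeds, 2)
  expect_true(any(seeds <= 30) && any(seeds > 30))   # one per blob
  expect_identical(seeds, selectSeeds(X, labels, plan, seed = 2))
  planAll <- transform(plan, n_to_sample = 60L)
  expect_equal(selectSeeds(X, labels, planAll, seed = 2), 1:60)
  planOver <- transform(plan, n_to_sample = 61L)
  expect_warning(s2 <- selectSeeds(X, labels, planOver, seed = 2), "clamped")
  expect_length(s2, 60)
})

test_that("edge penalties follow E_cm * E_bw^(-w) and reject flat bandwidths", {
  expect_equal(edgePenalties(1, E_cm = 1, E_bw = 10), 0.1)
  expect_equal(edgePenalties(0, E_cm = 1, E_bw = 10), 1)
  expect_equal(edgePenalties(0.5, E_cm = 2, E_bw = 10), 2 * 10^-0.5)
  w <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(edgePenalties(w)) < 0))
  expect_error(edgePenalties(w, E_bw = 1), "greater than 1")
  expect_error(edgePenalties(w, E_cm = 0), "positive")
})

test_that("PCST connects profitable seeds: hand-traced 3-node path", {
  p <- makeToyGraph("path", 3)               # weights 1 => penalty 0.1 per edge
  prizes <- c(10, 0, 10)
  res <- runPcst(p, prizes)
  expect_equal(res$nodes, 1:3)               # 19.8 beats any single seed's 10
  expect_equal(res$objective, 19.8)
  exact <- pcstExact(p, prizes)
  expect_equal(res$objective, exact$objective)
  expect_warning(empty <- runPcst(p, c(0, 0, 0)), "no prized")
  expect_length(empty$nodes, 0)
})

test_that("PCST returns one tree per seeded component and drops unprofitable seeds", {
  two <- edgesToAdjacency(rbind(c(1, 2), c(2, 3), c(4, 5)), 5)
  res <- runPcst(two, c(10, 0, 10, 10, 10))
  expect_setequal(res$nodes, 1:5)
  # no cross-component edges can exist; check selected edges stay within components
  comp <- c(1, 1, 1, 2, 2)
  expect_true(all(comp[res$edges[, 1]] == comp[res$edges[, 2]]))
  # a far seed behind an expensive path is dropped when unprofitable
  chain <- edgesToAdjacency(cbind(1:9, 2:10), 10, w = rep(1e-6, 9))  # penalty ~ 1 each
  res2 <- runPcst(chain, c(3, rep(0, 8), 3))
  expect_lt(length(res2$nodes), 10)          # connecting costs ~9, prizes 6
  expect_equal(res2$objective, pcstExact(chain, c(3, rep(0, 8), 3))$objective)
})

test_that("approximate PCST matches the exhaustive optimum on trees and stays within factor 2", {
  set.seed(3)
  for (n in 2:5) {
    graphs <- allConnectedGraphs(n)
    pick <- if (length(graphs) > 100) sample(graphs, 100) else graphs
    for (e in pick) {
      w <- runif(nrow(e), 0.05, 1)
      adj <- edgesToAdjacency(e, n, w)
      prizes <- numeric(n)
      nSeeds <- sample(n, 1)
      prizes[sample(n, nSeeds)] <- runif(nSeeds, 0.5, 10)
      approx <- runPcst(adj, prizes)
      exact <- pcstExact(adj, prizes)
      if (nrow(e) == n - 1) {
        expect_equal(approx$objective, exact$objective, tolerance = 1e-9)
      } else {
        expect_gte(approx$objective, 0.5 * exact$objective - 1e-9)
      }
      # connectivity of the selection within each component (union-find)
      if (length(approx$nodes) > 1) {
        sub <- edgesToAdjacency(approx$edges, max(approx$nodes))
        memb <- igraph::components(
          igraph::graph_from_adjacency_matrix(sub[approx$nodes, approx$nodes],
                                              mode = "undirected",
                                              weighted = TRUE))$membership
        full <- igraph::components(
          igraph::graph_from_adjacency_matrix(as.matrix(adj)[approx$nodes, approx$nodes] > 0,
                                              mode = "undirected"))$membership
        expect_true(all(tapply(memb, full, function(v) length(unique(v))) == 1))
      }
    }
  }
})

test_that("end-to-end subsampling keeps every cluster and full selected-set connectivity", {
  sim <- makeClusteredCounts(n_cells = 1000, n_genes = 800,
                             cluster_props = c(0.5, 0.3, 0.19, 0.01), seed = 4)
  rr <- suppressWarnings(runGraphPipeline(sim$counts, n_hvgs = 400, dims = 15,
                                          k = 15, seed = 1))
  sk <- subsampleCells(rr$graph, rr$labels, rr$reduced, max_rate = 0.05, seed = 1)
  expect_s4_class(sk, "SketchResult")
  expect_true(all(seedCells(sk) %in% selectedCells(sk)))
  expect_equal(nonzeroDegreeFraction(rr$graph, selectedCells(sk)), 100)
  for (cl in sort(unique(rr$labels)))
    expect_gt(sum(rr$labels[selectedCells(sk)] == cl), 0)
  # saturation: rate 1 with floor 1 selects everything
  skAll <- subsampleCells(rr$graph, rr$labels, rr$reduced, max_rate = 1,
                          min_rate = 1, seed = 1)
  expect_equal(selectedCells(skAll), seq_len(1000))
})
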