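# Independent oracles and small utilities used across the test suite. These
# deliberately re-derive quantities by brute force / closed form rather than
# calling the implementation paths they check.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  exp_ <- s(rowSums(tab)) * s(colSums(tab)) / choose(length(a), 2)
  (s(tab) - exp_) / ((s(rowSums(tab)) + s(colSums(tab))) / 2 - exp_)
}

# Best one-to-one greedy matching agreement between two labelings (percent).
matchedConcordance <- function(a, b) {
  m <- as.matrix(table(a, b))
  total <- 0
  for (i in seq_len(min(dim(m)))) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    total <- total + m[ij[1], ij[2]]
    m[ij[1], ] <- -1
    m[, ij[2]] <- -1
  }
  100 * total / length(a)
}

# All labeled connected graphs on n nodes (n <= 5), as m x 2 edge matrices.
allConnectedGraphs <- function(n) {
  if (n == 1) return(list(matrix(0L, 0, 2)))
  pairs <- t(combn(n, 2))
  np <- nrow(pairs)
  bits <- bitwShiftL(1L, 0:(np - 1))
  out <- list()
  for (code in seq_len(2^np - 1)) {
    e <- pairs[bitwAnd(code, bits) > 0, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(e))) parent[find(e[r, 1])] <- find(e[r, 2])
    if (length(unique(vapply(seq_len(n), find, 1L))) == 1)
      out[[length(out) + 1]] <- e
  }
  out
}

# Random connected graph on n nodes: random spanning tree plus extra edges.
randomConnectedGraph <- function(n, extra = n) {
  perm <- sample(n)
  e <- cbind(perm[-1], perm[vapply(2:n, function(i) sample(i - 1, 1), 1L)])
  pairs <- t(combn(n, 2))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  avail <- pairs[!(key(pairs) %in% key(e)), , drop = FALSE]
  if (extra > 0 && nrow(avail) > 0)
    e <- rbind(e, avail[sample(nrow(avail), min(extra, nrow(avail))), , drop = FALSE])
  e
}

edgesToAdjacency <- function(e, n, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(e))
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = c(w, w), dims = c(n, n))
}

# Exhaustive greedy agglomeration with the node-pair sampling distance:
# repeatedly merge the globally closest cluster pair. Returns the merge
# heights in merge order (finite merges only; stops when no connected pair
# remains). Independent of the package's nearest-neighbour-chain code.
parisGreedyOracle <- function(adj) {
  A <- as.matrix(adj)
  n <- nrow(A)
  wtot <- sum(A) / 2
  W <- A
  cw <- rowSums(A)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  while (sum(active) > 1) {
    act <- which(active)
    best <- Inf; bi <- 0L; bj <- 0L
    for (ii in seq_along(act)) {
      for (jj in seq_len(ii - 1)) {
        a <- act[ii]; b <- act[jj]
        if (W[a, b] > 0) {
          d <- (cw[a] / (2 * wtot)) * (cw[b] / (2 * wtot)) / (W[a, b] / wtot)
          if (d < best - 1e-15) { best <- d; bi <- b; bj <- a }
        }
      }
    }
    if (!is.finite(best)) break
    heights <- c(heights, best)
    W[bi, ] <- W[bi, ] + W[bj, ]
    W[, bi] <- W[, bi] + W[, bj]
    W[bi, bi] <- 0
    cw[bi] <- cw[bi] + cw[bj]
    active[bj] <- FALSE
  }
  heights
}

# Brute-force maximum-modularity bipartition of a small unweighted graph.
bestBipartitionModularity <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  n <- nrow(adj)
  best <- -Inf; bestPart <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    part <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    q <- igraph::modularity(g, part, weights = igraph::E(g)$weight)
    if (q > best) { best <- q; bestPart <- part }
  }
  list(modularity = best, partition = bestPart)
}

# Cosines of principal angles between the column spaces of two bases.
principalAngleCos <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  svd(crossprod(qu, qv))$d
}
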