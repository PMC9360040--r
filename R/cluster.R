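# Flat (Leiden) and hierarchical (Paris) clustering on the cell-cell graph.

#' Leiden clustering of the neighbourhood graph
#'
#' Delegates to igraph's Leiden implementation on the symmetrized weighted
#' graph (modularity objective). Our contract: deterministic for a fixed
#' seed, resolution parameter, labels relabelled 1..P by decreasing cluster
#' size.
#'
#' @param x a [NeighbourGraph-class] or symmetric sparse adjacency.
#' @param resolution positive resolution parameter (default 1).
#' @param seed RNG seed.
#' @param n_iterations Leiden refinement iterations.
#' @return integer vector of cluster labels (1-based, size-ordered).
#' @export
leidenCluster <- function(x, resolution = 1, seed = 42L, n_iterations = 2L) {
  adj <- symmetrizedAdjacency(x)
  if (nrow(adj) == 0) stop("empty graph", call. = FALSE)
  if (resolution <= 0) stop("'resolution' must be positive", call. = FALSE)
  g <- .igraphFromAdjacency(adj)
  if (igraph::ecount(g) == 0) stop("graph has no edges", call. = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(g)$weight,
                               n_iterations = n_iterations)
  .relabelBySize(igraph::membership(cl))
}

# --- Paris hierarchical clustering -----------------------------------------
#
# Distance between clusters a, b under the node-pair sampling model:
#     d(a, b) = p(a) p(b) / p(a, b)
# with p(a) = w(a) / (2 w_tot) the probability that a random edge endpoint
# lies in a (w(a) = summed incident edge weight) and p(a, b) =
# w(a, b) / w_tot the probability that a random edge joins a and b. Low
# d means a and b share more edge mass than their sizes predict, so they
# merge early. The distance is reducible, which is what makes the
# nearest-neighbour chain equivalent to exhaustive greedy agglomeration.

.parisDistance <- function(wa, wb, wab, wtot) {
  (wa / (2 * wtot)) * (wb / (2 * wtot)) / (wab / wtot)
}

#' Paris hierarchical graph clustering (nearest-neighbour chain)
#'
#' Builds a binary merge tree over the cells of the symmetrized weighted
#' graph. Pairs to merge are found with the nearest-neighbour chain: walk
#' from any cluster to its nearest neighbour until a reciprocal pair is
#' found, merge it, and resume the chain. Each connected component yields its
#' own dendrogram; multiple components are joined under a synthetic root at
#' height `Inf`. Merges are returned sorted by height (valid because the
#' distance is reducible).
#'
#' @param x a [NeighbourGraph-class] or symmetric sparse adjacency.
#' @return a [ParisDendrogram-class].
#' @seealso [cutDendrogram()], [exportNewick()]
#' @export
parisDendrogram <- function(x) {
  adj <- symmetrizedAdjacency(x)
  n <- nrow(adj)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  el <- .edgeList(adj)
  if (nrow(el) == 0) stop("graph has zero edges", call. = FALSE)
  wtot <- sum(el$w)

  nNodes <- 2L * n - 1L
  w <- numeric(nNodes)                 # cluster weights
  adjL <- vector("list", nNodes)       # named numeric vectors: neighbour -> weight
  for (i in seq_len(n)) adjL[[i]] <- numeric(0)
  for (r in seq_len(nrow(el))) {
    i <- el$i[r]; j <- el$j[r]; ww <- el$w[r]
    adjL[[i]][as.character(j)] <- ww
    adjL[[j]][as.character(i)] <- ww
    w[i] <- w[i] + ww
    w[j] <- w[j] + ww
  }
  active <- rep(FALSE, nNodes); active[seq_len(n)] <- TRUE
  nextNode <- n
  mergeA <- integer(n - 1L); mergeB <- integer(n - 1L); mergeH <- numeric(n - 1L)
  nm <- 0L

  nearest <- function(a, prefer = 0L) {
    nb <- adjL[[a]]
    if (length(nb) == 0) return(NULL)
    ids <- as.integer(names(nb))
    d <- .parisDistance(w[a], w[ids], nb, wtot)
    best <- min(d)
    cand <- ids[d <= best * (1 + 1e-12)]
    if (prefer %in% cand) prefer else min(cand)
  }

  doMerge <- function(a, b) {
    nextNode <<- nextNode + 1L
    m <- nextNode
    nb <- adjL[[a]]
    d <- .parisDistance(w[a], w[b], nb[[as.character(b)]], wtot)
    nm <<- nm + 1L
    mergeA[nm] <<- a; mergeB[nm] <<- b; mergeH[nm] <<- d
    merged <- adjL[[a]]
    for (k in names(adjL[[b]])) {
      merged[k] <- (if (k %in% names(merged)) merged[[k]] else 0) + adjL[[b]][[k]]
    }
    merged <- merged[!(names(merged) %in% as.character(c(a, b)))]
    adjL[[m]] <<- merged
    mc <- as.character(m)
    for (k in names(merged)) {
      ki <- as.integer(k)
      kn <- adjL[[ki]]
      kn <- kn[!(names(kn) %in% as.character(c(a, b)))]
      kn[mc] <- merged[[k]]
      adjL[[ki]] <<- kn
    }
    w[m] <<- w[a] + w[b]
    active[a] <<- FALSE; active[b] <<- FALSE; active[m] <<- TRUE
    adjL[[a]] <<- numeric(0); adjL[[b]] <<- numeric(0)
    m
  }

  chain <- integer(0)
  repeat {
    if (length(chain) == 0) {
      start <- which(active & vapply(adjL, length, 1L)[seq_len(nNodes)] > 0)[1]
      if (is.na(start)) break
      chain <- start
    }
    a <- chain[length(chain)]
    prev <- if (length(chain) >= 2) chain[length(chain) - 1L] else 0L
    b <- nearest(a, prefer = prev)
    if (is.null(b)) { chain <- chain[-length(chain)]; next }
    if (b == prev) {
      doMerge(min(a, b), max(a, b))
      chain <- chain[seq_len(length(chain) - 2L)]
    } else {
      chain <- c(chain, b)
    }
  }

  # join remaining roots (one per connected component) at +Inf
  roots <- which(active)
  while (length(roots) > 1) {
    nextNode <- nextNode + 1L
    nm <- nm + 1L
    mergeA[nm] <- roots[1]; mergeB[nm] <- roots[2]; mergeH[nm] <- Inf
    w[nextNode] <- w[roots[1]] + w[roots[2]]
    roots <- c(nextNode, roots[-(1:2)])
  }

  # sort merges by height (stable: equal heights keep chronological order,
  # so children always precede parents) and remap internal node ids
  ord <- order(mergeH[seq_len(nm)])
  remap <- seq_len(nNodes)
  remap[n + seq_len(nm)] <- n + match(seq_len(nm), ord)
  merges <- cbind(remap[mergeA[ord]], remap[mergeB[ord]])
  ids <- if (!is.null(rownames(adj))) rownames(adj) else character(0)
  new("ParisDendrogram", merges = merges, heights = mergeH[ord],
      nLeaves = as.integer(n), leafIds = ids)
}

#' Cut a dendrogram into k flat clusters
#'
#' Removes the `k - 1` highest merges (top-down cut); the resulting cuts are
#' nested: the cut at `k` refines the cut at `k - 1`.
#'
#' @param tree a [ParisDendrogram-class].
#' @param k number of clusters, `1 <= k <= n_cells`.
#' @return integer labels (1-based, relabelled by decreasing cluster size).
#' @export
cutDendrogram <- function(tree, k) {
  k <- .assertScalarCount(k, "k")
  n <- tree@nLeaves
  if (k > n) stop(sprintf("k (%d) exceeds the number of cells (%d)", k, n), call. = FALSE)
  parent <- seq_len(2L * n - 1L)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nKeep <- n - k
  for (t in seq_len(nKeep)) {
    m <- n + t
    parent[find(tree@merges[t, 1])] <- m
    parent[find(tree@merges[t, 2])] <- m
  }
  roots <- vapply(seq_len(n), find, 1L)
  .relabelBySize(match(roots, unique(roots)))
}

#' Cluster-to-cluster similarity from the graph
#'
#' `sim[p, q]` is the summed weight of edges with one endpoint in cluster p
#' and the other in q (each undirected edge counted once); the diagonal
#' holds within-cluster edge weight sums.
#'
#' @param x a [NeighbourGraph-class] or symmetric sparse adjacency.
#' @param labels integer cluster labels covering all graph nodes.
#' @return P x P symmetric matrix.
#' @export
clusterSimilarityGraph <- function(x, labels) {
  adj <- symmetrizedAdjacency(x)
  if (length(labels) != nrow(adj))
    stop("labels length must equal the number of graph nodes", call. = FALSE)
  labels <- as.integer(labels)
  P <- max(labels)
  el <- .edgeList(adj)
  p <- labels[el$i]; q <- labels[el$j]
  lo <- pmin(p, q); hi <- pmax(p, q)
  S <- as.matrix(Matrix::sparseMatrix(i = lo, j = hi, x = el$w, dims = c(P, P)))
  sim <- S + t(S)
  diag(sim) <- diag(S)
  sim
}

#' Export a dendrogram as Newick
#'
#' Leaves carry cell ids; branch lengths are height differences between a
#' node and its parent. Infinite component-joining heights are replaced by
#' twice the largest finite height for export.
#'
#' @param tree a [ParisDendrogram-class].
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly if written to file.
#' @export
exportNewick <- function(tree, file = NULL) {
  n <- tree@nLeaves
  h <- tree@heights
  finiteMax <- if (any(is.finite(h))) max(h[is.finite(h)], 0) else 1
  h[!is.finite(h)] <- 2 * max(finiteMax, 1)
  ids <- if (length(tree@leafIds)) tree@leafIds else sprintf("cell_%d", seq_len(n))
  nodeHeight <- c(rep(0, n), h)
  lab <- function(node) {
    if (node <= n) return(ids[node])
    t <- node - n
    a <- tree@merges[t, 1]; b <- tree@merges[t, 2]
    sprintf("(%s:%g,%s:%g)",
            lab(a), h[t] - nodeHeight[a],
            lab(b), h[t] - nodeHeight[b])
  }
  nwk <- paste0(lab(2L * n - 1L), ";")
  if (is.null(file)) return(nwk)
  writeLines(nwk, file)
  invisible(nwk)
}

#' Convert a ParisDendrogram to hclust
#'
#' @param x a [ParisDendrogram-class].
#' @param ... ignored.
#' @return an object of class `hclust` (infinite heights replaced as in
#'   [exportNewick()]).
#' @export
as.hclust.ParisDendrogram <- function(x, ...) {
  n <- x@nLeaves
  m <- x@merges
  hm <- matrix(0L, n - 1L, 2L)
  for (t in seq_len(n - 1L)) {
    for (s in 1:2) {
      v <- m[t, s]
      hm[t, s] <- if (v <= n) -v else v - n
    }
  }
  h <- x@heights
  finiteMax <- if (any(is.finite(h))) max(h[is.finite(h)], 0) else 1
  h[!is.finite(h)] <- 2 * max(finiteMax, 1)
  ord <- integer(0)
  walk <- function(node) {
    if (node <= n) { ord <<- c(ord, node); return(invisible()) }
    t <- node - n
    walk(m[t, 1]); walk(m[t, 2])
  }
  walk(2L * n - 1L)
  structure(list(merge = hm, height = h, order = ord,
                 labels = if (length(x@leafIds)) x@leafIds else as.character(seq_len(n)),
                 method = "paris", call = match.call(),
                 dist.method = "node-pair sampling"),
            class = "hclust")
}
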