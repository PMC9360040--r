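# Topology-assisted cell downsampling: per-node topology scores, per-cluster
# sampling rates, seed selection by sub-clustering, and a prize-collecting
# Steiner tree (PCST) connecting the seeds.

# Binary (0/1) undirected adjacency view of a graph-like object.
.binaryAdjacency <- function(x) {
  adj <- symmetrizedAdjacency(x)
  adj@x[] <- 1
  adj
}

#' n-neighbourhood degree (NND)
#'
#' The 1-neighbourhood degree of a node is the summed degree of all nodes
#' connected to it; larger `n_steps` extend the sum over the whole <= n-step
#' neighbourhood (neighbours of neighbours, excluding the node itself). NND
#' captures the density of connections around a node; isolated nodes score 0.
#'
#' @param x a [NeighbourGraph-class] or symmetric sparse adjacency.
#' @param n_steps positive number of steps (default 2).
#' @return numeric per-node NND.
#' @export
neighbourhoodDegree <- function(x, n_steps = 2L) {
  n_steps <- .assertScalarCount(n_steps, "n_steps")
  A <- .binaryAdjacency(x)
  deg <- Matrix::rowSums(A)
  reach <- A
  if (n_steps > 1) {
    for (s in seq_len(n_steps - 1L)) {
      reach <- reach %*% A + reach
      reach@x[] <- 1
      reach <- Matrix::drop0(reach)
    }
    Matrix::diag(reach) <- 0
    reach <- Matrix::drop0(reach)
  }
  as.numeric(reach %*% deg)
}

#' Neighbourhood connectedness (NC)
#'
#' For each node, the sum over its neighbours of the shared-nearest-neighbour
#' Jaccard similarity `|N(v) inter N(u)| / |N(v) union N(u)|`. Nodes whose
#' neighbours are strongly interconnected score high; isolated nodes score 0.
#'
#' @param x a [NeighbourGraph-class] or symmetric sparse adjacency.
#' @return numeric per-node NC.
#' @export
neighbourhoodConnectedness <- function(x) {
  A <- .binaryAdjacency(x)
  deg <- Matrix::rowSums(A)
  shared <- A %*% A           # common-neighbour counts for every node pair
  el <- .edgeList(A)
  s <- shared[cbind(el$i, el$j)]
  uni <- deg[el$i] + deg[el$j] - s
  J <- ifelse(uni > 0, s / uni, 0)
  nc <- numeric(nrow(A))
  agg <- rowsum(c(J, J), c(el$i, el$j))
  nc[as.integer(rownames(agg))] <- agg[, 1]
  nc
}

#' Per-cluster sampling plan
#'
#' Cluster medians of NND and NC are rescaled across clusters to \[1, 2\]
#' (`s(m) = 1 + (m - min)/(max - min)`; all 1 when medians are equal), and
#' the sampling rate of cluster c is
#' `clip(base_rate / (s(nnd_c) * s(nc_c)), min_rate, max_rate)` — denser,
#' more redundant clusters are sampled at lower rates. Every non-empty
#' cluster is allotted at least one cell.
#'
#' @param labels integer cluster labels per cell.
#' @param topology list with per-node `nnd` and `nc` (see
#'   [neighbourhoodDegree()], [neighbourhoodConnectedness()]).
#' @param base_rate nominal sampling rate (default 0.01).
#' @param min_rate,max_rate clipping bounds; defaults `base_rate / 10` and
#'   `base_rate`, so `base_rate` acts as the maximum sampling rate.
#' @return data.frame with one row per cluster: `cluster`, `size`,
#'   `median_nnd`, `median_nc`, `rate`, `n_to_sample`.
#' @export
samplingPlan <- function(labels, topology, base_rate = 0.01,
                         min_rate = base_rate / 10, max_rate = base_rate) {
  if (max_rate <= 0 || max_rate > 1) stop("'max_rate' must lie in (0, 1]", call. = FALSE)
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  sizes <- as.vector(table(factor(labels, levels = cl)))
  if (any(sizes == 0)) stop("empty cluster in labels", call. = FALSE)
  medNnd <- vapply(cl, function(c) median(topology$nnd[labels == c]), 0)
  medNc <- vapply(cl, function(c) median(topology$nc[labels == c]), 0)
  rescale <- function(m) {
    if (max(m) - min(m) < 1e-12) rep(1, length(m))
    else 1 + (m - min(m)) / (max(m) - min(m))
  }
  rate <- pmin(max_rate, pmax(min_rate, base_rate / (rescale(medNnd) * rescale(medNc))))
  data.frame(cluster = cl, size = sizes, median_nnd = medNnd, median_nc = medNc,
             rate = rate, n_to_sample = pmin(sizes, pmax(1L, round(rate * sizes))))
}

#' Select seed cells by sub-clustering
#'
#' Each cluster is sub-clustered (k-means in the reduced space) into
#' `n_to_sample` groups and the medoid of each group — the member cell
#' nearest the group centroid — becomes a seed.
#'
#' @param reduced a [ReducedMatrix-class] or coordinate matrix.
#' @param labels integer cluster labels per cell.
#' @param plan a [samplingPlan()] data.frame.
#' @param seed RNG seed.
#' @return integer vector of seed cell indices.
#' @export
selectSeeds <- function(reduced, labels, plan, seed = 42L) {
  X <- if (is(reduced, "ReducedMatrix")) coords(reduced) else .asDense(reduced)
  labels <- as.integer(labels)
  seeds <- integer(0)
  set.seed(seed)
  for (r in seq_len(nrow(plan))) {
    cells <- which(labels == plan$cluster[r])
    ns <- plan$n_to_sample[r]
    if (ns > length(cells)) {
      warning(sprintf("cluster %d: n_to_sample clamped to cluster size", plan$cluster[r]))
      ns <- length(cells)
    }
    if (ns >= length(cells)) { seeds <- c(seeds, cells); next }
    Xi <- X[cells, , drop = FALSE]
    ns <- min(ns, nrow(unique(Xi)))
    km <- suppressWarnings(tryCatch(
      kmeans(Xi, centers = ns, iter.max = 50L, nstart = 1L),
      error = function(e)   # duplicate sampled starts: seed from distinct rows
        kmeans(Xi, centers = unique(Xi)[seq_len(ns), , drop = FALSE],
               iter.max = 50L)))
    for (g in seq_len(ns)) {
      members <- which(km$cluster == g)
      dd <- rowSums(sweep(Xi[members, , drop = FALSE], 2, km$centers[g, ])^2)
      seeds <- c(seeds, cells[members[which.min(dd)]])
    }
  }
  sort(unique(seeds))
}

#' Edge penalties for the PCST instance
#'
#' `E_p = E_cm * E_bw^(-E_w)`: penalties are positive and strictly
#' decreasing in the edge weight, so well-supported edges are cheap to keep.
#' Defaults follow the reported settings `E_cm = 1`, `E_bw = 10`.
#'
#' @param weights edge weights in (0, 1\].
#' @param E_cm edge cost multiplier (> 0).
#' @param E_bw edge bandwidth (> 1; values <= 1 would not discriminate).
#' @return numeric penalties, one per edge.
#' @export
edgePenalties <- function(weights, E_cm = 1, E_bw = 10) {
  if (E_cm <= 0) stop("'E_cm' must be positive", call. = FALSE)
  if (E_bw <= 1) stop("'E_bw' must be greater than 1", call. = FALSE)
  E_cm * E_bw^(-weights)
}

# Exact PCST by exhaustion over connected node subsets (oracle for small
# graphs): for a fixed node set the cheapest connecting edge set is the MST
# of the induced subgraph (Prim), so the objective of a subset is
# sum(prizes) - mst_cost. Feasible up to ~12 nodes.
.pcstBruteForce <- function(el, n, prizes) {
  if (n > 12) stop("brute-force PCST supports at most 12 nodes", call. = FALSE)
  C <- matrix(Inf, n, n)
  C[cbind(el$i, el$j)] <- el$cost
  C[cbind(el$j, el$i)] <- el$cost
  best <- list(objective = 0, nodes = integer(0), edges = matrix(0L, 0, 2))
  bits <- bitwShiftL(1L, 0:(n - 1))
  for (code in seq_len(2^n - 1)) {
    nodes <- which(bitwAnd(code, bits) > 0)
    m <- length(nodes)
    if (m == 1) {
      obj <- prizes[nodes]; edges <- matrix(0L, 0, 2)
    } else {
      sub <- C[nodes, nodes, drop = FALSE]
      inTree <- c(TRUE, rep(FALSE, m - 1))
      mind <- sub[1, ]; from <- rep(1L, m)
      cost <- 0; ok <- TRUE
      edges <- matrix(0L, m - 1, 2)
      for (step in seq_len(m - 1)) {
        cand <- which(!inTree)
        v <- cand[which.min(mind[cand])]
        if (!is.finite(mind[v])) { ok <- FALSE; break }
        cost <- cost + mind[v]
        edges[step, ] <- c(nodes[from[v]], nodes[v])
        inTree[v] <- TRUE
        upd <- !inTree & sub[v, ] < mind
        mind[upd] <- sub[v, upd]; from[upd] <- v
      }
      if (!ok) next  # induced subgraph disconnected
      obj <- sum(prizes[nodes]) - cost
    }
    if (obj > best$objective + 1e-12)
      best <- list(objective = obj, nodes = nodes, edges = edges)
  }
  best
}

# Exact prize-collecting subtree of a tree by rooted DP: best(v) = prize(v) +
# sum_c max(0, best(c) - cost(v,c)); the optimum over all connected subtrees
# is max_v best(v) (every subtree has a unique topmost node).
.pcstTreeDp <- function(treeEdges, treeCosts, nodes, prizes) {
  nn <- length(nodes)
  pos <- match(seq_len(max(nodes)), nodes)
  adj <- vector("list", nn)
  for (r in seq_len(nrow(treeEdges))) {
    a <- pos[treeEdges[r, 1]]; b <- pos[treeEdges[r, 2]]
    adj[[a]] <- rbind(adj[[a]], c(b, treeCosts[r]))
    adj[[b]] <- rbind(adj[[b]], c(a, treeCosts[r]))
  }
  best <- numeric(nn)
  parent <- rep(0L, nn)
  order <- integer(nn)
  # iterative DFS from node 1 for a bottom-up order
  stack <- 1L; seen <- logical(nn); top <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    top <- top + 1L; order[top] <- v
    if (!is.null(adj[[v]])) for (r in seq_len(nrow(adj[[v]]))) {
      u <- adj[[v]][r, 1]
      if (!seen[u]) { parent[u] <- v; stack <- c(stack, u) }
    }
  }
  for (v in rev(order)) {
    best[v] <- prizes[nodes[v]]
    if (!is.null(adj[[v]])) for (r in seq_len(nrow(adj[[v]]))) {
      u <- adj[[v]][r, 1]
      if (parent[u] == v) best[v] <- best[v] + max(0, best[u] - adj[[v]][r, 2])
    }
  }
  rootPos <- which.max(best)
  keep <- logical(nn)
  edgesKeep <- matrix(0L, 0, 2)
  stack2 <- rootPos
  while (length(stack2)) {
    v <- stack2[length(stack2)]; stack2 <- stack2[-length(stack2)]
    keep[v] <- TRUE
    if (!is.null(adj[[v]])) for (r in seq_len(nrow(adj[[v]]))) {
      u <- adj[[v]][r, 1]
      if (parent[u] == v && best[u] - adj[[v]][r, 2] > 0) {
        edgesKeep <- rbind(edgesKeep, c(nodes[v], nodes[u]))
        stack2 <- c(stack2, u)
      }
    }
  }
  cost <- if (nrow(edgesKeep)) {
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    sum(treeCosts[match(key(edgesKeep), key(treeEdges))])
  } else 0
  list(nodes = nodes[keep], edges = edgesKeep,
       objective = sum(prizes[nodes[keep]]) - cost)
}

#' Run the prize-collecting Steiner tree solver
#'
#' Approximate unrooted PCST on the cell-cell graph: within each connected
#' component holding at least one prized node, the prized nodes are joined by
#' a shortest-path Steiner construction (metric closure, MST, path
#' expansion, MST of the expansion), then an exact prize-collecting dynamic
#' program on the resulting tree prunes branches whose cost exceeds their
#' prize. On tree-shaped graphs the result is the exact PCST optimum. The
#' objective maximised is `sum(prizes[selected]) - sum(penalties[tree edges])`.
#'
#' @param x a [NeighbourGraph-class] or symmetric sparse adjacency whose
#'   entries are edge weights in (0, 1].
#' @param prizes per-node prize (>= 0); typically `prize` on seeds, 0 elsewhere.
#' @param E_cm,E_bw edge-penalty parameters, see [edgePenalties()].
#' @return list with `nodes` (selected cell indices), `edges` (m x 2 tree
#'   edges), `objective`.
#' @export
runPcst <- function(x, prizes, E_cm = 1, E_bw = 10) {
  adj <- symmetrizedAdjacency(x)
  n <- nrow(adj)
  if (length(prizes) != n) stop("prizes must have one entry per node", call. = FALSE)
  if (all(prizes <= 0)) {
    warning("no prized nodes; empty selection")
    return(list(nodes = integer(0), edges = matrix(0L, 0, 2), objective = 0))
  }
  el <- .edgeList(adj)
  el$cost <- edgePenalties(el$w, E_cm, E_bw)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(el$i, el$j))
  igraph::E(g)$cost <- el$cost
  comp <- igraph::components(g)$membership
  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  elKeys <- edgeKey(el$i, el$j)

  allNodes <- integer(0); allEdges <- matrix(0L, 0, 2); objective <- 0
  for (cmp in unique(comp)) {
    members <- which(comp == cmp)
    terms <- members[prizes[members] > 0]
    if (length(terms) == 0) next
    if (length(terms) == 1) {
      allNodes <- c(allNodes, terms)
      objective <- objective + prizes[terms]
      next
    }
    # metric closure over the prized nodes (symmetrized: Dijkstra rounding)
    D <- igraph::distances(g, v = terms, to = terms, weights = igraph::E(g)$cost)
    D <- (D + t(D)) / 2
    cg <- igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
    cmst <- igraph::mst(cg, weights = igraph::E(cg)$weight)
    cel <- igraph::as_edgelist(cmst, names = FALSE)
    # expand each closure edge into its shortest path
    pathNodes <- integer(0)
    for (r in seq_len(nrow(cel))) {
      sp <- igraph::shortest_paths(g, from = terms[cel[r, 1]], to = terms[cel[r, 2]],
                                   weights = igraph::E(g)$cost, output = "vpath")
      pathNodes <- c(pathNodes, as.integer(sp$vpath[[1]]))
    }
    hNodes <- sort(unique(pathNodes))
    keep <- el$i %in% hNodes & el$j %in% hNodes
    sub <- el[keep, , drop = FALSE]
    hg <- igraph::make_empty_graph(n = length(hNodes), directed = FALSE)
    hg <- igraph::add_edges(hg, rbind(match(sub$i, hNodes), match(sub$j, hNodes)))
    hmst <- igraph::mst(hg, weights = sub$cost)
    em <- igraph::as_edgelist(hmst, names = FALSE)
    treeEdges <- cbind(hNodes[em[, 1]], hNodes[em[, 2]])
    treeCosts <- el$cost[match(edgeKey(treeEdges[, 1], treeEdges[, 2]), elKeys)]
    res <- .pcstTreeDp(treeEdges, treeCosts, hNodes, prizes)
    allNodes <- c(allNodes, res$nodes)
    allEdges <- rbind(allEdges, res$edges)
    objective <- objective + res$objective
  }
  list(nodes = sort(unique(allNodes)), edges = allEdges, objective = objective)
}

#' Exact PCST by exhaustive search (small-graph oracle)
#'
#' Enumerates connected node subsets (cheapest connector of a subset is the
#' induced MST); intended for graphs of at most 12 nodes.
#'
#' @inheritParams runPcst
#' @return as [runPcst()].
#' @export
pcstExact <- function(x, prizes, E_cm = 1, E_bw = 10) {
  adj <- symmetrizedAdjacency(x)
  el <- .edgeList(adj)
  el$cost <- edgePenalties(el$w, E_cm, E_bw)
  res <- .pcstBruteForce(el, nrow(adj), prizes)
  list(nodes = res$nodes, edges = res$edges, objective = res$objective)
}

#' Topology-assisted downsampling (end-to-end)
#'
#' Orchestrates the full sketching procedure: NND and NC per node, a
#' per-cluster sampling plan, seed selection by sub-clustering, edge
#' penalties, and the PCST connecting the seeds. Seeds receive a uniform
#' prize (default 10); selected cells are the PCST tree nodes (seeds plus
#' Steiner cells), one connected tree per graph component.
#'
#' @param graph a [NeighbourGraph-class] (smoothed) or symmetric adjacency.
#' @param labels integer cluster labels per cell.
#' @param reduced reduced coordinates used for sub-clustering.
#' @param max_rate maximum per-cluster sampling rate (default 0.01).
#' @param min_rate minimum rate (default `max_rate / 10`).
#' @param prize seed prize (default 10).
#' @param E_cm,E_bw edge-penalty parameters (defaults 1 and 10).
#' @param n_steps NND step count (default 2).
#' @param seed RNG seed.
#' @return a [SketchResult-class].
#' @export
subsampleCells <- function(graph, labels, reduced, max_rate = 0.01,
                           min_rate = max_rate / 10, prize = 10,
                           E_cm = 1, E_bw = 10, n_steps = 2L, seed = 42L) {
  topology <- list(nnd = neighbourhoodDegree(graph, n_steps),
                   nc = neighbourhoodConnectedness(graph))
  plan <- samplingPlan(labels, topology, base_rate = max_rate,
                       min_rate = min_rate, max_rate = max_rate)
  seeds <- selectSeeds(reduced, labels, plan, seed = seed)
  n <- if (is(graph, "NeighbourGraph")) nCells(graph) else nrow(graph)
  # a component holding a single seed can never grow a tree, which would
  # leave that sketch cell isolated; give every multi-cell component with
  # exactly one seed a second landmark (the cell farthest from the first)
  comp <- .components(symmetrizedAdjacency(graph))
  X <- if (is(reduced, "ReducedMatrix")) coords(reduced) else .asDense(reduced)
  for (cmp in unique(comp)) {
    members <- which(comp == cmp)
    sIn <- intersect(seeds, members)
    if (length(members) >= 2 && length(sIn) == 1) {
      dd <- rowSums(sweep(X[members, , drop = FALSE], 2, X[sIn, ])^2)
      seeds <- sort(c(seeds, members[which.max(dd)]))
    }
  }
  prizes <- numeric(n)
  prizes[seeds] <- prize
  res <- runPcst(graph, prizes, E_cm = E_cm, E_bw = E_bw)
  plan$n_selected <- vapply(plan$cluster, function(c)
    sum(labels[res$nodes] == c), 0L)
  em <- res$edges
  storage.mode(em) <- "integer"
  new("SketchResult", seeds = as.integer(seeds), selected = as.integer(res$nodes),
      selectedEdges = em, perCluster = plan)
}
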