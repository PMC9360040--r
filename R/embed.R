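# Pluggable 2D/3D embedding engines driven by the neighbourhood graph.
#
# The module's contract: the engine receives the symmetrized graph and the
# initial embedding unchanged (neighbours are never recomputed here),
# `n_iter = 0` returns the initial coordinates untouched, and a fixed seed
# reproduces coordinates exactly. Engine internals are external: "fr" is
# igraph's weighted Fruchterman-Reingold layout, "umap" is uwot (optional),
# "graph-tsne" has no available engine and raises a capability error.

#' Embed cells from the neighbourhood graph
#'
#' @param x a [NeighbourGraph-class] or symmetric sparse adjacency.
#' @param init initial embedding from [initialEmbedding()] (or a plain
#'   cells x dim coordinate matrix).
#' @param engine `"fr"` (force-directed, default), `"umap"` (requires uwot),
#'   or `"graph-tsne"` (no engine available).
#' @param n_iter engine iterations; 0 returns `init` unchanged.
#' @param seed RNG seed.
#' @param params named list of extra engine arguments.
#' @return cells x dim matrix of finite coordinates.
#' @export
embedCells <- function(x, init, engine = c("fr", "umap", "graph-tsne"),
                       n_iter = 250L, seed = 42L, params = list()) {
  engine <- match.arg(engine)
  initCoords <- if (is.list(init)) init$coords else .asDense(init)
  adj <- symmetrizedAdjacency(x)
  if (nrow(initCoords) != nrow(adj))
    stop("init coordinates do not match the graph size", call. = FALSE)
  if (n_iter == 0) return(initCoords)

  out <- switch(engine,
    "fr" = {
      g <- .igraphFromAdjacency(adj)
      set.seed(seed)
      args <- c(list(graph = g, coords = initCoords, niter = as.integer(n_iter),
                     dim = ncol(initCoords), weights = igraph::E(g)$weight),
                params)
      do.call(igraph::layout_with_fr, args)
    },
    "umap" = {
      if (!requireNamespace("uwot", quietly = TRUE))
        stop("engine 'umap' requires the uwot package, which is not installed",
             call. = FALSE)
      if (!is(x, "NeighbourGraph"))
        stop("engine 'umap' needs a NeighbourGraph (directed KNN lists)", call. = FALSE)
      n <- nCells(x)
      nn <- list(idx = cbind(seq_len(n), knnIndices(x)),
                 dist = cbind(0, knnDistances(x)))
      set.seed(seed)
      args <- c(list(X = NULL, nn_method = nn, init = initCoords,
                     n_epochs = as.integer(n_iter),
                     n_components = ncol(initCoords), n_threads = 1),
                params)
      do.call(uwot::umap, args)
    },
    "graph-tsne" = stop("engine 'graph-tsne' is not available: no graph t-SNE engine is installed",
                        call. = FALSE)
  )
  out <- .asDense(out)
  if (any(!is.finite(out))) stop("engine produced non-finite coordinates", call. = FALSE)
  out
}
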