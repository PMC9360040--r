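# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  as.integer(x)
}

# Dense numeric matrix from anything matrix-like.
.asDense <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# Blockwise Euclidean distances between rows of a and rows of b (dense).
.crossDist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Row ranges for streaming a matrix of n rows in blocks of row_block rows.
.rowBlocks <- function(n, row_block) {
  row_block <- .assertScalarCount(row_block, "row_block")
  starts <- seq.int(1L, n, by = row_block)
  lapply(starts, function(s) c(s, min(n, s + row_block - 1L)))
}

# Relabel integer cluster labels to 1..P by decreasing cluster size
# (ties broken by first appearance) for stable reporting.
.relabelBySize <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.vector(tab), match(names(tab), names(tab)))]
  match(as.character(labels), ord)
}

# Upper-triangle edge list (i < j, weight) of a symmetric sparse matrix.
.edgeList <- function(adj) {
  adj <- methods::as(methods::as(adj, "generalMatrix"), "TsparseMatrix")
  i <- adj@i + 1L; j <- adj@j + 1L; w <- adj@x
  keep <- i < j & w != 0
  data.frame(i = i[keep], j = j[keep], w = w[keep])
}

.igraphFromAdjacency <- function(adj) {
  el <- .edgeList(adj)
  g <- igraph::make_empty_graph(n = nrow(adj), directed = FALSE)
  g <- igraph::add_edges(g, rbind(el$i, el$j))
  igraph::E(g)$weight <- el$w
  g
}

# Membership vector of connected components of a symmetric adjacency.
.components <- function(adj) {
  igraph::components(.igraphFromAdjacency(adj))$membership
}
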