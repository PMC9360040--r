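# Synthetic-data and toy-graph generators. Every generator is a pure
# function of its arguments plus the seed, so all downstream modules are
# testable without external downloads.

#' Clustered negative-binomial scRNA-seq counts
#'
#' Emulates a droplet scRNA-seq count matrix with discrete cell populations:
#' per-gene baseline means are gamma-distributed; each cluster up-regulates
#' its own disjoint `de_fraction` of genes by a fixed `fold`; per-cell
#' library-size factors are log-normal (sigma 0.3, multiplicative); counts
#' are negative binomial parameterised by (mean, dispersion), i.e.
#' `var = mu + dispersion * mu^2`. Cluster sizes are a multinomial draw with
#' the given proportions, so rare clusters (e.g. 1%) can be emulated
#' directly.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param cluster_props cluster proportions summing to 1.
#' @param de_fraction fraction of genes up-regulated per cluster (default 0.1).
#' @param fold fold-change of up-regulated genes (default 4).
#' @param nb_mean mean of the per-gene baseline means (default 0.5).
#' @param nb_dispersion NB dispersion (default 0.5).
#' @param lib_sigma SD of the log-normal library factor (default 0.3).
#' @param seed RNG seed; fully determines the output.
#' @return list with `counts` (cells x genes), `labels` (true cluster per
#'   cell, 1-based), `de_genes` (list of up-regulated gene indices per
#'   cluster).
#' @export
makeClusteredCounts <- function(n_cells = 1000L, n_genes = 1000L,
                                cluster_props = c(0.4, 0.3, 0.2, 0.1),
                                de_fraction = 0.1, fold = 4,
                                nb_mean = 0.5, nb_dispersion = 0.5,
                                lib_sigma = 0.3, seed = 42L) {
  if (abs(sum(cluster_props) - 1) > 1e-9)
    stop("cluster proportions must sum to 1", call. = FALSE)
  set.seed(seed)
  K <- length(cluster_props)
  labels <- sample(seq_len(K), n_cells, replace = TRUE, prob = cluster_props)
  baseMu <- rgamma(n_genes, shape = 2, scale = nb_mean / 2)
  nDe <- round(de_fraction * n_genes)
  pool <- sample.int(n_genes)
  de <- vector("list", K)
  for (k in seq_len(K)) {
    if (nDe == 0) { de[[k]] <- integer(0); next }
    # disjoint DE programs while the gene pool lasts, then recycle
    if (length(pool) < nDe) pool <- sample.int(n_genes)
    de[[k]] <- pool[seq_len(nDe)]
    pool <- pool[-seq_len(nDe)]
  }
  lib <- rlnorm(n_cells, 0, lib_sigma)
  counts <- matrix(0, n_cells, n_genes)
  for (k in seq_len(K)) {
    cells <- which(labels == k)
    if (!length(cells)) next
    mu <- baseMu
    mu[de[[k]]] <- mu[de[[k]]] * fold
    mug <- outer(lib[cells], mu)
    counts[cells, ] <- rnbinom(length(mug), mu = mug, size = 1 / nb_dispersion)
  }
  dimnames(counts) <- list(sprintf("cell_%d", seq_len(n_cells)),
                           sprintf("gene_%d", seq_len(n_genes)))
  list(counts = counts, labels = labels, de_genes = de)
}

#' Continuum (trajectory) counts
#'
#' Emulates a differentiating population: each cell sits at a pseudotime in
#' \[0, 1\]; gene programs are defined at `n_stages` anchor points and
#' interpolate linearly between adjacent anchors, so expression changes
#' smoothly along the trajectory and the KNN graph is dominated by
#' pseudotime-adjacent cells. A designated subset of genes is monotone in
#' pseudotime (log-linear) for correlation checks.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_stages number of anchor stages (>= 2, default 5).
#' @param nb_mean,nb_dispersion,lib_sigma as in [makeClusteredCounts()].
#' @param monotone_fraction fraction of genes made monotone in pseudotime.
#' @param seed RNG seed.
#' @return list with `counts`, `pseudotime` (per cell, in \[0, 1\]),
#'   `monotone_genes` (indices), `stage` (nearest anchor per cell).
#' @export
makeTrajectoryCounts <- function(n_cells = 1000L, n_genes = 1000L, n_stages = 5L,
                                 nb_mean = 0.5, nb_dispersion = 0.5,
                                 lib_sigma = 0.3, monotone_fraction = 0.1,
                                 seed = 42L) {
  if (n_stages < 2) stop("'n_stages' must be >= 2", call. = FALSE)
  set.seed(seed)
  pt <- runif(n_cells)
  logAnchor <- matrix(rnorm(n_stages * n_genes, mean = log(nb_mean), sd = 1),
                      n_stages, n_genes)
  nMono <- round(monotone_fraction * n_genes)
  mono <- sample.int(n_genes, nMono)
  slope <- sample(c(-2.5, 2.5), nMono, replace = TRUE)
  for (j in seq_along(mono)) {
    # monotone programs get a higher baseline so the trend is not drowned in
    # sampling zeros at typical scRNA-seq count depths
    logAnchor[, mono[j]] <- log(nb_mean * 4) + slope[j] * seq(-0.5, 0.5, length.out = n_stages)
  }
  pos <- pt * (n_stages - 1) + 1
  loIdx <- pmin(floor(pos), n_stages - 1)
  frac <- pos - loIdx
  logMu <- (1 - frac) * logAnchor[loIdx, , drop = FALSE] +
    frac * logAnchor[loIdx + 1, , drop = FALSE]
  lib <- rlnorm(n_cells, 0, lib_sigma)
  mu <- exp(logMu) * lib
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                   n_cells, n_genes)
  dimnames(counts) <- list(sprintf("cell_%d", seq_len(n_cells)),
                           sprintf("gene_%d", seq_len(n_genes)))
  list(counts = counts, pseudotime = pt, monotone_genes = mono,
       stage = round(pos))
}

#' Binary-ish scATAC peak counts
#'
#' scATAC emulation: clustered negative-binomial counts (with an inflated
#' feature count) binarised at > 0, so the matrix is sparse and near-binary
#' as peak-by-cell accessibility matrices are. Intended for TF-IDF / LSI
#' tests.
#'
#' @param n_cells,n_peaks dimensions (peaks default to 4x a gene panel).
#' @param cluster_props,de_fraction,fold,seed as in [makeClusteredCounts()].
#' @return list with `counts` (0/1 matrix) and `labels`.
#' @export
makeAtacCounts <- function(n_cells = 500L, n_peaks = 2000L,
                           cluster_props = c(0.5, 0.5), de_fraction = 0.2,
                           fold = 6, seed = 42L) {
  sim <- makeClusteredCounts(n_cells = n_cells, n_genes = n_peaks,
                             cluster_props = cluster_props,
                             de_fraction = de_fraction, fold = fold,
                             nb_mean = 0.2, nb_dispersion = 1, seed = seed)
  counts <- (sim$counts > 0) * 1
  dimnames(counts) <- list(sprintf("cell_%d", seq_len(n_cells)),
                           sprintf("peak_%d", seq_len(n_peaks)))
  list(counts = counts, labels = sim$labels)
}

#' Toy graphs with exact named topology
#'
#' @param topology one of `"clique"`, `"star"`, `"path"`,
#'   `"two_cliques_bridge"`, `"grid"`.
#' @param size topology size: clique/path/star node or leaf count; for
#'   `two_cliques_bridge` a pair `c(n1, n2)`; for `grid` a pair
#'   `c(rows, cols)`.
#' @param weight constant edge weight (default 1) or a vector recycled over
#'   edges in construction order.
#' @return symmetric sparse adjacency (`dgCMatrix`).
#' @export
makeToyGraph <- function(topology = c("clique", "star", "path",
                                      "two_cliques_bridge", "grid"),
                         size, weight = 1) {
  topology <- match.arg(topology)
  edges <- switch(topology,
    clique = t(utils::combn(size, 2)),
    star = cbind(1L, 1L + seq_len(size)),   # size leaves around node 1
    path = cbind(seq_len(size - 1), 2:size),
    two_cliques_bridge = {
      n1 <- size[1]; n2 <- size[2]
      rbind(t(utils::combn(n1, 2)),
            t(utils::combn(n2, 2)) + n1,
            c(n1, n1 + 1L))
    },
    grid = {
      r <- size[1]; cc <- size[2]
      id <- function(i, j) (i - 1L) * cc + j
      e <- NULL
      for (i in seq_len(r)) for (j in seq_len(cc)) {
        if (j < cc) e <- rbind(e, c(id(i, j), id(i, j + 1)))
        if (i < r) e <- rbind(e, c(id(i, j), id(i + 1, j)))
      }
      e
    }
  )
  n <- max(edges)
  w <- rep_len(weight, nrow(edges))
  Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                       j = c(edges[, 2], edges[, 1]),
                       x = c(w, w), dims = c(n, n))
}
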