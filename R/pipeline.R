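# Convenience orchestration of the standard scRNA-seq workflow:
# normalisation -> HVG selection -> streamed PCA -> KNN graph -> edge
# smoothing -> Leiden. Every step is an exported function; this wrapper just
# wires the defaults used throughout the package's own evaluations.

#' Run the standard graph pipeline
#'
#' @param x raw counts: an [AssayStore-class] or matrix (cells x genes).
#' @param n_hvgs number of highly variable genes (default 2500; clamped with
#'   a warning when fewer genes are eligible).
#' @param dims PCA dimensions (default 25).
#' @param k KNN neighbours (default 21).
#' @param resolution Leiden resolution (default 1).
#' @param S library-size scaling factor (default 1000), log transform applied.
#' @param backend KNN backend (default `"exact"`).
#' @param row_block streamed block size.
#' @param seed seed for PCA sketching, KNN backend and Leiden.
#' @return list with `hvg` (selection data.frame), `reduced`
#'   ([ReducedMatrix-class]), `graph` (smoothed [NeighbourGraph-class]),
#'   `labels` (Leiden labels, size-ordered).
#' @examples
#' sim <- makeClusteredCounts(n_cells = 300, n_genes = 300, seed = 1)
#' res <- runGraphPipeline(sim$counts, n_hvgs = 100, dims = 10, k = 10)
#' table(res$labels, sim$labels)
#' @export
runGraphPipeline <- function(x, n_hvgs = 2500L, dims = 25L, k = 21L,
                             resolution = 1, S = 1000, backend = "exact",
                             row_block = 2000L, seed = 42L) {
  fids <- if (is(x, "AssayStore")) featureIds(x) else colnames(x)
  gs <- geneStats(x, S = S, log_transform = TRUE, row_block = row_block)
  hvg <- selectHvgs(gs$means, gs$variances, feature_ids = fids, n_top = n_hvgs)
  blockFun <- function(block, rows) normalizeLibrarySize(block, S = S, log_transform = TRUE)
  reduced <- fitIncrementalPca(x, d = dims, feat_mask = hvg$selected,
                               block_fun = blockFun, row_block = row_block,
                               seed = seed)
  graph <- smoothEdgeWeights(buildKnnGraph(reduced, k = k, backend = backend,
                                           seed = seed))
  labels <- leidenCluster(graph, resolution = resolution, seed = seed)
  list(hvg = hvg, reduced = reduced, graph = graph, labels = labels)
}

#' Fit a reference model for KNN mapping
#'
#' Prepares everything [mapTargetCounts()] needs: reference HVGs, the
#' common-total rescaling, the reference scaler + PCA, the saved KNN index
#' and the reference graph.
#'
#' @param counts reference raw counts (cells x genes) or store.
#' @param n_hvgs,dims,k,S,seed as in [runGraphPipeline()].
#' @return list with `hvg_ids`, `hvg_mask`, `rescaled`, `reduced`, `index`,
#'   `graph`.
#' @export
fitReferenceModel <- function(counts, n_hvgs = 2500L, dims = 25L, k = 11L,
                              S = 1000, seed = 42L) {
  m <- if (is(counts, "AssayStore")) loadCounts(counts) else .asDense(counts)
  fids <- colnames(m) %||% sprintf("gene_%d", seq_len(ncol(m)))
  colnames(m) <- fids
  gs <- geneStats(m, S = S, log_transform = TRUE)
  hvg <- selectHvgs(gs$means, gs$variances, feature_ids = fids, n_top = n_hvgs)
  resc <- rescaleToCommonTotal(normalizeLibrarySize(m, S = S), hvg$selected)
  reduced <- fitIncrementalPca(resc, d = dims, seed = seed)
  index <- buildKnnIndex(coords(reduced))
  graph <- smoothEdgeWeights(buildKnnGraph(reduced, k = k, seed = seed))
  list(hvg_ids = fids[hvg$selected], hvg_mask = hvg$selected,
       rescaled = resc, reduced = reduced, index = index, graph = graph)
}

#' Map target counts onto a fitted reference model
#'
#' Rescales the target over the reference HVGs, optionally applies CORAL,
#' transforms into the reference PCA space with the reference's scaler and
#' loadings (never refit), and maps onto the saved reference index.
#'
#' @param ref a model from [fitReferenceModel()].
#' @param counts target raw counts (cells x genes; gene ids must cover the
#'   reference HVGs).
#' @param k reference neighbours per target (default 11).
#' @param coral apply CORAL correction (default `TRUE`).
#' @param S library-size scaling factor.
#' @return list with `mapping` ([MappingResult-class]), `target_coords`,
#'   `coral` (the [coralCorrect()] output, or `NULL`).
#' @export
mapTargetCounts <- function(ref, counts, k = 11L, coral = TRUE, S = 1000) {
  m <- if (is(counts, "AssayStore")) loadCounts(counts) else .asDense(counts)
  fids <- colnames(m) %||% sprintf("gene_%d", seq_len(ncol(m)))
  if (!all(ref$hvg_ids %in% fids))
    stop("target is missing reference HVGs", call. = FALSE)
  m <- m[, match(ref$hvg_ids, fids), drop = FALSE]
  resc <- rescaleToCommonTotal(normalizeLibrarySize(m, S = S), NULL)
  if (coral) {
    cc <- coralCorrect(ref$rescaled, resc)
    tc <- transformCells(ref$reduced, cc$T_corrected, apply_scaler = FALSE)
  } else {
    cc <- NULL
    tc <- transformCells(ref$reduced, resc, apply_scaler = TRUE)
  }
  list(mapping = mapCells(ref$index, tc, k = k), target_coords = tc, coral = cc)
}
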