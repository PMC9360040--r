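# Chunked on-disk storage of count matrices.
#
# Layout of a store directory:
#   manifest.json                  dims, chunk grid, assay names, default assay
#   cells.tsv                      cell ids + attributes (shared by all assays)
#   assays/<name>/features.tsv     feature ids + attributes
#   assays/<name>/chunks/c<r>_<c>  gzip-compressed dense chunk (serialized)
#
# Chunks are dense and compressed individually; no sparse/dense
# interconversion happens anywhere in the pipeline.

.manifestPath <- function(path) file.path(path, "manifest.json")

.readManifest <- function(path) {
  mf <- .manifestPath(path)
  if (!file.exists(mf)) stop(sprintf("'%s' is not a store (no manifest)", path), call. = FALSE)
  jsonlite::read_json(mf, simplifyVector = TRUE)
}

.writeManifest <- function(path, manifest) {
  jsonlite::write_json(manifest, .manifestPath(path), auto_unbox = TRUE, digits = NA)
}

.chunkFile <- function(store, ri, ci) {
  file.path(store@path, "assays", store@assay, "chunks", sprintf("c%d_%d.rds", ri, ci))
}

#' Create a chunked on-disk store from a count matrix
#'
#' Splits `counts` (cells as rows, features as columns) into a grid of dense
#' chunks of shape `chunk_shape`, compresses each chunk and writes it to its
#' own file under `path`. Additional assays can be added to an existing store
#' by calling `createStore()` again with the same `path` and a new `assay`
#' name; the first assay written becomes the default assay unless
#' `default = TRUE` is given later.
#'
#' @param counts numeric matrix (or sparse `Matrix`) of non-negative counts,
#'   cells x features.
#' @param path directory to create (or extend).
#' @param assay assay name, e.g. `"RNA"` or `"ATAC"`.
#' @param cell_ids,feature_ids unique identifiers; default to dimnames or
#'   `cell_1..n` / `feat_1..n`.
#' @param chunk_shape integer pair: rows x columns per chunk. The default
#'   2000 x 2000 trades loading cycles (larger chunks) against peak memory
#'   (smaller chunks).
#' @param compressed gzip-compress chunks (default `TRUE`).
#' @param default make this assay the store's default assay.
#' @return an [AssayStore-class] for the written assay.
#' @examples
#' st <- createStore(matrix(0:5, 3, 2), tempfile(), chunk_shape = c(2, 2))
#' nCells(st)
#' @export
createStore <- function(counts, path, assay = "RNA",
                        cell_ids = NULL, feature_ids = NULL,
                        chunk_shape = c(2000L, 2000L),
                        compressed = TRUE, default = NA) {
  counts <- .asDense(counts)
  if (any(counts < 0)) stop("count values must be non-negative", call. = FALSE)
  n <- nrow(counts); p <- ncol(counts)
  cell_ids <- cell_ids %||% rownames(counts) %||% sprintf("cell_%d", seq_len(n))
  feature_ids <- feature_ids %||% colnames(counts) %||% sprintf("feat_%d", seq_len(p))
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("feature ids must be unique", call. = FALSE)
  if (length(cell_ids) != n) stop("cell_ids length must equal number of rows", call. = FALSE)
  if (length(feature_ids) != p) stop("feature_ids length must equal number of columns", call. = FALSE)
  chunk_shape <- as.integer(chunk_shape)

  newStore <- !dir.exists(path) || !file.exists(.manifestPath(path))
  if (newStore) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(version = 1L, n_cells = n, default_assay = assay, assays = list())
    write.table(data.frame(id = cell_ids, valid = TRUE),
                file.path(path, "cells.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    manifest <- .readManifest(path)
    if (manifest$n_cells != n)
      stop(sprintf("store has %d cells but counts has %d rows", manifest$n_cells, n),
           call. = FALSE)
  }
  if (isTRUE(default)) manifest$default_assay <- assay
  manifest$assays[[assay]] <- list(n_features = p,
                                   chunk_rows = chunk_shape[1],
                                   chunk_cols = chunk_shape[2],
                                   compressed = compressed)
  adir <- file.path(path, "assays", assay)
  dir.create(file.path(adir, "chunks"), recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(id = feature_ids, valid = TRUE),
              file.path(adir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  st <- new("AssayStore", path = path, assay = assay,
            dims = c(n, p), chunkShape = chunk_shape, compressed = compressed)
  rblocks <- .rowBlocks(n, chunk_shape[1])
  cblocks <- .rowBlocks(p, chunk_shape[2])
  for (ri in seq_along(rblocks)) {
    for (ci in seq_along(cblocks)) {
      rb <- rblocks[[ri]]; cb <- cblocks[[ci]]
      chunk <- counts[rb[1]:rb[2], cb[1]:cb[2], drop = FALSE]
      dimnames(chunk) <- NULL
      saveRDS(chunk, .chunkFile(st, ri, ci),
              compress = if (compressed) "gzip" else FALSE)
    }
  }
  .writeManifest(path, manifest)
  st
}

#' Open an existing store
#'
#' @param path store directory.
#' @param assay assay name; defaults to the store's default assay.
#' @return an [AssayStore-class].
#' @export
openStore <- function(path, assay = NULL) {
  manifest <- .readManifest(path)
  assay <- assay %||% manifest$default_assay
  a <- manifest$assays[[assay]]
  if (is.null(a)) stop(sprintf("assay '%s' not found in store", assay), call. = FALSE)
  new("AssayStore", path = path, assay = assay,
      dims = c(as.integer(manifest$n_cells), as.integer(a$n_features)),
      chunkShape = c(as.integer(a$chunk_rows), as.integer(a$chunk_cols)),
      compressed = isTRUE(a$compressed))
}

#' List assays of a store
#' @param path store directory.
#' @return character vector of assay names; the default assay first.
#' @export
listAssays <- function(path) {
  manifest <- .readManifest(path)
  nm <- names(manifest$assays)
  c(manifest$default_assay, setdiff(nm, manifest$default_assay))
}

#' Cell and feature attribute tables
#'
#' Cell attributes (one row per cell, shared across assays) live at the store
#' root; feature attributes under the assay group. Both carry a logical
#' `valid` column used as the default mask by downstream steps.
#'
#' @param store an [AssayStore-class].
#' @param value a data.frame with one row per cell/feature and an `id` column.
#' @return a data.frame.
#' @export
cellTable <- function(store) {
  read.delim(file.path(store@path, "cells.tsv"), stringsAsFactors = FALSE)
}

#' @rdname cellTable
#' @export
featureTable <- function(store) {
  read.delim(file.path(store@path, "assays", store@assay, "features.tsv"),
             stringsAsFactors = FALSE)
}

#' @rdname cellTable
#' @export
`cellTable<-` <- function(store, value) {
  stopifnot(is.data.frame(value), nrow(value) == nCells(store), "id" %in% names(value))
  write.table(value, file.path(store@path, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  store
}

#' @rdname cellTable
#' @export
`featureTable<-` <- function(store, value) {
  stopifnot(is.data.frame(value), nrow(value) == nFeatures(store), "id" %in% names(value))
  write.table(value, file.path(store@path, "assays", store@assay, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  store
}

#' @rdname accessors
#' @export
setMethod("cellIds", "AssayStore", function(x, ...) cellTable(x)$id)

#' @rdname accessors
#' @export
setMethod("featureIds", "AssayStore", function(x, ...) featureTable(x)$id)

# Assemble a dense block of contiguous rows (all columns) from chunk files.
.readRowBlock <- function(store, r1, r2) {
  cr <- store@chunkShape[1]; cc <- store@chunkShape[2]
  p <- store@dims[2]
  out <- matrix(0, r2 - r1 + 1L, p)
  ri1 <- (r1 - 1L) %/% cr + 1L
  ri2 <- (r2 - 1L) %/% cr + 1L
  ncb <- (p - 1L) %/% cc + 1L
  for (ri in ri1:ri2) {
    cs <- (ri - 1L) * cr + 1L
    ce <- min(store@dims[1], ri * cr)
    sel1 <- max(r1, cs); sel2 <- min(r2, ce)
    for (ci in seq_len(ncb)) {
      chunk <- readRDS(.chunkFile(store, ri, ci))
      col1 <- (ci - 1L) * cc + 1L
      out[(sel1 - r1 + 1L):(sel2 - r1 + 1L), col1:(col1 + ncol(chunk) - 1L)] <-
        chunk[(sel1 - cs + 1L):(sel2 - cs + 1L), , drop = FALSE]
    }
  }
  out
}

#' Stream a matrix (or store) in contiguous row blocks
#'
#' `streamBlocks()` applies `FUN` to successive dense row blocks; vertical
#' concatenation of the blocks reproduces the full matrix exactly, so any
#' statistic accumulated across blocks is independent of `row_block`.
#' `iterChunks()` returns an iterator with `nextChunk()` for manual pulls.
#'
#' @param x an [AssayStore-class] or an in-memory matrix.
#' @param row_block rows per block (1 <= row_block <= n_cells).
#' @param FUN function of `(block, rows)` where `rows` is the row index range.
#' @param ... passed on to `FUN`.
#' @return `streamBlocks()`: invisible list of `FUN` results, in block order.
#' @examples
#' m <- matrix(1:20, 10, 2)
#' s <- Reduce(`+`, streamBlocks(m, 3, function(block, rows) colSums(block)))
#' stopifnot(all(s == colSums(m)))
#' @export
setGeneric("streamBlocks", function(x, row_block, FUN, ...) standardGeneric("streamBlocks"))

#' @rdname streamBlocks
#' @export
setMethod("streamBlocks", "AssayStore", function(x, row_block, FUN, ...) {
  blocks <- .rowBlocks(x@dims[1], row_block)
  invisible(lapply(blocks, function(b) {
    FUN(.readRowBlock(x, b[1], b[2]), b[1]:b[2], ...)
  }))
})

#' @rdname streamBlocks
#' @export
setMethod("streamBlocks", "matrix", function(x, row_block, FUN, ...) {
  blocks <- .rowBlocks(nrow(x), row_block)
  invisible(lapply(blocks, function(b) {
    FUN(.asDense(x[b[1]:b[2], , drop = FALSE]), b[1]:b[2], ...)
  }))
})

#' @rdname streamBlocks
#' @param store an [AssayStore-class].
#' @return `iterChunks()`: a list with `nextChunk()` returning
#'   `list(block, rows)` or `NULL` when exhausted, and `reset()`.
#' @export
iterChunks <- function(store, row_block) {
  n <- if (is(store, "AssayStore")) store@dims[1] else nrow(store)
  blocks <- .rowBlocks(n, row_block)
  i <- 0L
  fetch <- if (is(store, "AssayStore")) {
    function(b) .readRowBlock(store, b[1], b[2])
  } else {
    function(b) .asDense(store[b[1]:b[2], , drop = FALSE])
  }
  list(
    nextChunk = function() {
      i <<- i + 1L
      if (i > length(blocks)) return(NULL)
      b <- blocks[[i]]
      list(block = fetch(b), rows = b[1]:b[2])
    },
    reset = function() i <<- 0L,
    n_chunks = length(blocks)
  )
}

#' Materialise the full count matrix of a store
#'
#' Convenience for small stores (tests, examples); streams chunks and binds
#' them, attaching cell/feature ids as dimnames.
#'
#' @param store an [AssayStore-class].
#' @return a dense matrix, cells x features.
#' @export
loadCounts <- function(store) {
  out <- matrix(0, store@dims[1], store@dims[2])
  streamBlocks(store, store@chunkShape[1], function(block, rows) {
    out[rows, ] <<- block
    NULL
  })
  dimnames(out) <- list(cellIds(store), featureIds(store))
  out
}

#' Export a cell/feature subset of a store
#'
#' Streams the source store and writes the masked submatrix (and consistently
#' subset attribute tables) to a new store directory.
#'
#' @param store source [AssayStore-class].
#' @param cell_mask logical per cell; must select at least one cell.
#' @param feat_mask logical per feature.
#' @param path destination directory.
#' @param chunk_shape chunk shape of the destination (defaults to source's).
#' @return the new [AssayStore-class].
#' @export
exportSubset <- function(store, cell_mask = NULL, feat_mask = NULL, path,
                         chunk_shape = NULL) {
  cell_mask <- cell_mask %||% rep(TRUE, nCells(store))
  feat_mask <- feat_mask %||% rep(TRUE, nFeatures(store))
  if (length(cell_mask) != nCells(store) || length(feat_mask) != nFeatures(store))
    stop("mask lengths must match store dimensions", call. = FALSE)
  if (!any(cell_mask)) stop("cell_mask selects no cells", call. = FALSE)
  if (!any(feat_mask)) stop("feat_mask selects no features", call. = FALSE)
  chunk_shape <- chunk_shape %||% store@chunkShape
  sub <- matrix(0, sum(cell_mask), sum(feat_mask))
  offset <- 0L
  streamBlocks(store, store@chunkShape[1], function(block, rows) {
    keep <- cell_mask[rows]
    if (any(keep)) {
      nk <- sum(keep)
      sub[offset + seq_len(nk), ] <<- block[keep, feat_mask, drop = FALSE]
      offset <<- offset + nk
    }
    NULL
  })
  out <- createStore(sub, path, assay = store@assay,
                     cell_ids = cellIds(store)[cell_mask],
                     feature_ids = featureIds(store)[feat_mask],
                     chunk_shape = chunk_shape, compressed = store@compressed)
  ct <- cellTable(store)[cell_mask, , drop = FALSE]
  ft <- featureTable(store)[feat_mask, , drop = FALSE]
  cellTable(out) <- ct
  featureTable(out) <- ft
  out
}
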