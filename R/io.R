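# Readers and writers for standard count-matrix formats.

#' Read a count matrix into a chunked store
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx`}{a directory (or a `.mtx` file) with `matrix.mtx` plus
#'     `barcodes.tsv` and `features.tsv`/`genes.tsv` sidecars. The Matrix
#'     Market triplet is features x cells (10x convention) when the sidecar
#'     lengths say so, otherwise cells x features; the result is always
#'     cells x features.}
#'   \item{`csv`}{dense CSV/TSV with a header row of feature ids and the
#'     first column holding cell ids.}
#'   \item{`h5`}{10x-style HDF5 feature-barcode matrix (CSC over cells);
#'     requires the `rhdf5` package.}
#' }
#'
#' @param path input file or directory.
#' @param format one of `"mtx"`, `"csv"`, `"h5"`.
#' @param out_path store directory to create; defaults to a tempdir.
#' @param assay assay name for the store.
#' @param chunk_shape chunk shape for the store.
#' @return an [AssayStore-class].
#' @export
readCounts <- function(path, format = c("mtx", "csv", "h5"),
                       out_path = tempfile("store_"), assay = "RNA",
                       chunk_shape = c(2000L, 2000L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("path '%s' does not exist", path), call. = FALSE)
  parsed <- switch(format,
    mtx = .readMtx(path),
    csv = .readCsv(path),
    h5 = .read10xH5(path)
  )
  createStore(parsed$counts, out_path, assay = assay,
              cell_ids = parsed$cell_ids, feature_ids = parsed$feature_ids,
              chunk_shape = chunk_shape)
}

.sidecar <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop(sprintf("no sidecar found in '%s' (tried: %s)", dir,
               paste(candidates, collapse = ", ")), call. = FALSE)
}

.readMtx <- function(path) {
  if (dir.exists(path)) {
    dir <- path
    mtx <- .sidecar(dir, c("matrix.mtx", "counts.mtx"))
  } else {
    dir <- dirname(path)
    mtx <- path
  }
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop(sprintf("malformed MTX file '%s': %s",
                                                 mtx, conditionMessage(e)), call. = FALSE))
  barcodes <- readLines(.sidecar(dir, c("barcodes.tsv", "barcodes.txt")))
  feats <- read.delim(.sidecar(dir, c("features.tsv", "genes.tsv", "features.txt")),
                      header = FALSE, stringsAsFactors = FALSE)
  feature_ids <- feats[[1]]
  if (nrow(m) == length(feature_ids) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)  # 10x convention: features x cells
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(feature_ids))) {
    stop(sprintf(paste0("MTX dimensions (%d x %d) do not match sidecars ",
                        "(%d barcodes, %d features)"),
                 nrow(m), ncol(m), length(barcodes), length(feature_ids)),
         call. = FALSE)
  }
  list(counts = .asDense(m), cell_ids = barcodes, feature_ids = feature_ids)
}

.readCsv <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("malformed CSV '%s': need cell-id column plus features", path),
                         call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("malformed CSV '%s': non-numeric count values", path),
                           call. = FALSE)
  list(counts = m, cell_ids = ids, feature_ids = colnames(df)[-1])
}

.read10xH5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading 10x HDF5 requires the 'rhdf5' package, which is not installed",
         call. = FALSE)
  groups <- rhdf5::h5ls(path, recursive = FALSE)
  grp <- groups$name[groups$otype == "H5I_GROUP"][1]
  rd <- function(what) rhdf5::h5read(path, paste0(grp, "/", what))
  shape <- as.integer(rd("shape"))  # features x cells
  m <- Matrix::sparseMatrix(
    i = as.integer(rd("indices")) + 1L,
    p = as.integer(rd("indptr")),
    x = as.numeric(rd("data")),
    dims = shape
  )
  feature_ids <- tryCatch(as.character(rd("features/id")),
                          error = function(e) as.character(rd("genes")))
  barcodes <- as.character(rd("barcodes"))
  if (nrow(m) != length(feature_ids) || ncol(m) != length(barcodes))
    stop("HDF5 matrix shape does not match features/barcodes", call. = FALSE)
  list(counts = .asDense(Matrix::t(m)), cell_ids = barcodes, feature_ids = feature_ids)
}

#' Write a store as Matrix Market triplet plus sidecars
#'
#' Emits `matrix.mtx` (features x cells, 10x convention, 1-based indices per
#' the MTX standard), `barcodes.tsv` and `features.tsv` into `dir`.
#'
#' @param store an [AssayStore-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeCountsMtx <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(loadCounts(store), sparse = TRUE)
  Matrix::writeMM(Matrix::t(m), file.path(dir, "matrix.mtx"))
  writeLines(cellIds(store), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = featureIds(store), name = featureIds(store)),
              file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
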