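#' Accessors for cellgraphkit classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param ... ignored.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nCells", function(x, ...) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x, ...) standardGeneric("nFeatures"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x, ...) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("knnIndices", function(x, ...) standardGeneric("knnIndices"))

#' @rdname accessors
#' @export
setGeneric("knnDistances", function(x, ...) standardGeneric("knnDistances"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x, ...) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("recallValue", function(x, ...) standardGeneric("recallValue"))

#' @rdname accessors
#' @export
setGeneric("seedCells", function(x, ...) standardGeneric("seedCells"))

#' @rdname accessors
#' @export
setGeneric("selectedCells", function(x, ...) standardGeneric("selectedCells"))

#' Symmetrized adjacency of a graph-like object
#'
#' Returns the undirected weighted adjacency matrix of a cell-cell graph. For
#' a [NeighbourGraph-class] the directed smoothed weights `w1`, `w2` of a
#' reciprocated pair are combined by the fuzzy union `w1 + w2 - w1 * w2`
#' (one-sided edges keep their weight), so two cells are connected if at
#' least one lists the other among its k neighbours.
#'
#' @param x a [NeighbourGraph-class] or a symmetric `dgCMatrix`.
#' @param ... ignored.
#' @return a symmetric sparse `dgCMatrix` with zero diagonal.
#' @export
setGeneric("symmetrizedAdjacency", function(x, ...) standardGeneric("symmetrizedAdjacency"))

#' @rdname accessors
#' @export
setMethod("nCells", "AssayStore", function(x, ...) x@dims[1])

#' @rdname accessors
#' @export
setMethod("nFeatures", "AssayStore", function(x, ...) x@dims[2])

#' @rdname accessors
#' @export
setMethod("coords", "ReducedMatrix", function(x, ...) x@coords)

#' @rdname accessors
#' @export
setMethod("nCells", "NeighbourGraph", function(x, ...) nrow(x@knnIdx))

#' @rdname accessors
#' @export
setMethod("knnIndices", "NeighbourGraph", function(x, ...) x@knnIdx)

#' @rdname accessors
#' @export
setMethod("knnDistances", "NeighbourGraph", function(x, ...) x@knnDist)

#' @rdname accessors
#' @export
setMethod("edgeWeights", "NeighbourGraph", function(x, ...) x@weights)

#' @rdname accessors
#' @export
setMethod("recallValue", "NeighbourGraph", function(x, ...) x@recall)

#' @rdname accessors
#' @export
setMethod("seedCells", "SketchResult", function(x, ...) x@seeds)

#' @rdname accessors
#' @export
setMethod("selectedCells", "SketchResult", function(x, ...) x@selected)

#' @rdname accessors
#' @export
setMethod("knnIndices", "MappingResult", function(x, ...) x@knnIdx)

#' @rdname accessors
#' @export
setMethod("knnDistances", "MappingResult", function(x, ...) x@knnDist)

#' @rdname accessors
#' @export
setMethod("edgeWeights", "MappingResult", function(x, ...) x@weights)
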