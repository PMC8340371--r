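#' Accessor generics
#'
#' Small accessor family for the graph, distribution and score classes:
#' `geneIds()` and `targetIds()` return identifier vectors, `phiS()` and
#' `phiI()` the proportionality and similarity matrices, `weightMatrix()`
#' the bipartite weights, `adjacencyMatrix()`, `nodeIds()` and `nodeKinds()`
#' the heterogeneous graph pieces, `pPos()`/`pNeg()` the channel vectors,
#' `scoresPos()`/`scoresNeg()` the score matrices, and `provenance()` the
#' recorded construction parameters.
#'
#' @param x an object of one of the dcRWR classes.
#' @return the slot contents named above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname accessors
#' @export
setGeneric("phiS", function(x) standardGeneric("phiS"))

#' @rdname accessors
#' @export
setGeneric("phiI", function(x) standardGeneric("phiI"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("targetKind", function(x) standardGeneric("targetKind"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("nodeKinds", function(x) standardGeneric("nodeKinds"))

#' @rdname accessors
#' @export
setGeneric("pPos", function(x) standardGeneric("pPos"))

#' @rdname accessors
#' @export
setGeneric("pNeg", function(x) standardGeneric("pNeg"))

#' @rdname accessors
#' @export
setGeneric("scoresPos", function(x) standardGeneric("scoresPos"))

#' @rdname accessors
#' @export
setGeneric("scoresNeg", function(x) standardGeneric("scoresNeg"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
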