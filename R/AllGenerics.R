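#' @rdname GenotypeMatrix
#' @param x,object a GenotypeMatrix (or graph/topology object, see methods).
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("eventNames", function(x) standardGeneric("eventNames"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("eventInfo", function(x) standardGeneric("eventInfo"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("dataKind", function(x) standardGeneric("dataKind"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Accessors shared by graph-like objects
#'
#' \code{graphNodes} and \code{graphEdges} return the node ids and the edge
#' table of a \linkS4class{PrimaFacieGraph} or \linkS4class{MutationalGraph};
#' \code{memberMap} returns the mapping from (aggregate) node ids to the
#' original event ids they stand for, for those and for
#' \linkS4class{GenotypeMatrix}.
#'
#' @param x a graph object (or GenotypeMatrix for \code{memberMap}).
#' @return \code{graphNodes}: character vector; \code{graphEdges}:
#'   data.frame; \code{memberMap}: named list; \code{nodeMarginals}: named
#'   numeric vector.
#' @name graph-accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graph-accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graph-accessors
#' @export
setGeneric("memberMap", function(x) standardGeneric("memberMap"))

#' @rdname graph-accessors
#' @export
setGeneric("nodeMarginals", function(x) standardGeneric("nodeMarginals"))

#' Topology accessors
#'
#' @param x a \linkS4class{Topology}.
#' @return \code{rootNodes}: ids of parentless nodes; \code{parentMap}:
#'   named character vector child -> parent (NA for roots); \code{nodeProb}:
#'   named activation probabilities; \code{trueEdges}: data.frame of the
#'   direct parent -> child edges.
#' @name topology-accessors
#' @export
setGeneric("rootNodes", function(x) standardGeneric("rootNodes"))

#' @rdname topology-accessors
#' @export
setGeneric("parentMap", function(x) standardGeneric("parentMap"))

#' @rdname topology-accessors
#' @export
setGeneric("nodeProb", function(x) standardGeneric("nodeProb"))

#' @rdname topology-accessors
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))

#' @rdname NoiseRates
#' @param x a NoiseRates object.
#' @export
setGeneric("fpRate", function(x) standardGeneric("fpRate"))

#' @rdname NoiseRates
#' @export
setGeneric("fnRate", function(x) standardGeneric("fnRate"))
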