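#' @import methods
#' @importFrom stats phyper rbinom runif setNames
#' @importFrom utils read.table write.table
NULL

.EVENT_KINDS <- c("mutation", "indel", "CNA", "epigenetic", "other")
.DATA_KINDS <- c("single_cell", "multi_region")

#' GenotypeMatrix: binary presence/absence genotype data
#'
#' An m x n binary matrix over \{0, 1, NA\} storing the presence (1) or
#' absence (0) of n somatic events (mutations, indels, CNAs, epigenetic
#' states, ...) across m samples, where samples are either single cells or
#' spatially separated bulk regions. NA marks a missing (uncalled) entry.
#'
#' @slot values integer matrix with samples on rows and events on columns;
#'   dimnames carry the sample and event ids.
#' @slot events data.frame with one row per event and columns \code{id},
#'   \code{label}, \code{kind} (one of mutation, indel, CNA, epigenetic,
#'   other).
#' @slot dataKind either \code{"single_cell"} or \code{"multi_region"}.
#' @slot memberMap named list mapping each event id to the ids of the
#'   original events it represents; entries of length > 1 arise when
#'   \code{\link{aggregateEvents}} merges events with identical profiles.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(
    values = "matrix",
    events = "data.frame",
    dataKind = "character",
    memberMap = "list"
  )
)

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) < 1L || ncol(v) < 1L)
    msg <- c(msg, "matrix must have at least one sample and one event")
  bad <- !(v %in% c(0L, 1L) | is.na(v))
  if (any(bad))
    msg <- c(msg, "entries must be 0, 1 or NA")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "sample ids must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "event ids must be present and unique")
  if (!identical(object@events$id, colnames(v)))
    msg <- c(msg, "events data.frame must match matrix columns")
  if (any(!object@events$kind %in% .EVENT_KINDS))
    msg <- c(msg, "unknown event kind")
  if (any(!nzchar(object@events$label)))
    msg <- c(msg, "event labels must be non-empty")
  if (length(object@dataKind) != 1L || !object@dataKind %in% .DATA_KINDS)
    msg <- c(msg, "dataKind must be 'single_cell' or 'multi_region'")
  if (!all(names(object@memberMap) %in% colnames(v)))
    msg <- c(msg, "memberMap names must be event ids")
  if (length(msg)) msg else TRUE
})

#' NoiseRates: genotyping error rates
#'
#' False-positive rate (a 0 observed as 1, e.g. sequencing artefacts) and
#' false-negative rate (a 1 observed as 0, e.g. allelic dropout in
#' single-cell data). Rates are supplied a priori and used to invert the
#' misclassification model when estimating probabilities; identifiability
#' requires fp + fn < 1.
#'
#' @slot fp false-positive probability in [0, 1).
#' @slot fn false-negative probability in [0, 1).
#'
#' @aliases NoiseRates-class
#' @exportClass NoiseRates
setClass("NoiseRates", representation(fp = "numeric", fn = "numeric"))

setValidity("NoiseRates", function(object) {
  fp <- object@fp; fn <- object@fn
  if (length(fp) != 1L || length(fn) != 1L)
    return("fp and fn must be scalars")
  if (is.na(fp) || is.na(fn) || fp < 0 || fn < 0 || fp >= 1 || fn >= 1)
    return("rates must lie in [0, 1)")
  if (fp + fn >= 1)
    return("fp + fn must be < 1 (noise model not identifiable otherwise)")
  TRUE
})

#' Topology: a ground-truth generative tree or forest
#'
#' Forest over event ids used by the simulator and the evaluation harness:
#' each node has at most one parent (roots have none) and an activation
#' probability, the chance that the event is acquired given its parent is
#' present (for roots: the marginal chance the founding event is present in
#' a cell).
#'
#' @slot nodes character vector of node ids.
#' @slot parent named character vector over all nodes; NA for roots.
#' @slot nodeProb named numeric vector of activation probabilities in [0,1].
#'
#' @aliases Topology-class
#' @exportClass Topology
setClass("Topology",
  representation(nodes = "character", parent = "character",
                 nodeProb = "numeric")
)

setValidity("Topology", function(object) {
  n <- object@nodes
  msg <- character()
  if (anyDuplicated(n)) msg <- c(msg, "node ids must be unique")
  if (!identical(sort(names(object@parent)), sort(n)) ||
      !identical(sort(names(object@nodeProb)), sort(n)))
    msg <- c(msg, "parent and nodeProb must be named over all nodes")
  p <- object@parent[!is.na(object@parent)]
  if (any(!p %in% n)) msg <- c(msg, "parents must be nodes")
  if (!any(is.na(object@parent))) msg <- c(msg, "at least one root required")
  if (any(object@nodeProb < 0 | object@nodeProb > 1, na.rm = TRUE))
    msg <- c(msg, "node probabilities must lie in [0, 1]")
  # walking parent pointers must terminate: forest, no cycles
  if (!length(msg)) {
    for (v in n) {
      seen <- character(); cur <- v
      while (!is.na(object@parent[[cur]])) {
        if (cur %in% seen) return("parent map contains a cycle")
        seen <- c(seen, cur)
        cur <- object@parent[[cur]]
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' PrimaFacieGraph: candidate orderings passing Suppes' conditions
#'
#' Directed graph over events whose edge x -> y records that x is a
#' statistically supported candidate temporal predecessor of y: the
#' temporal-priority condition p(x) > p(y) and the association condition
#' p(y|x) > p(y|not x) both passed a bootstrap Mann-Whitney test. Edges
#' carry the two p-values, an information-theoretic weight, and a
#' confidence score used downstream for loop removal. May contain cycles.
#'
#' @slot nodes character vector of event ids.
#' @slot edges data.frame with columns from, to, weight, p_temporal,
#'   p_association, confidence.
#' @slot nodeMarginals named numeric of (noise-corrected) event marginals.
#' @slot memberMap named list from event ids to aggregated member ids.
#' @slot params list recording alpha, B, weight kind and noise rates.
#'
#' @aliases PrimaFacieGraph-class
#' @exportClass PrimaFacieGraph
setClass("PrimaFacieGraph",
  representation(nodes = "character", edges = "data.frame",
                 nodeMarginals = "numeric", memberMap = "list",
                 params = "list")
)

setValidity("PrimaFacieGraph", function(object) {
  .validGraphEdges(object@nodes, object@edges)
})

#' MutationalGraph: an acyclic model of temporal ordering
#'
#' Weighted directed acyclic graph over events (and aggregate events) whose
#' edges give the inferred temporal precedence of somatic alterations.
#' Tree/forest outputs (Edmonds, Gabow) have in-degree at most 1
#' everywhere; Chow-Liu and Prim outputs may contain confluences (nodes
#' with several parents) expressing uncertain precedence.
#'
#' @slot nodes character vector of node ids.
#' @slot edges data.frame with columns from, to, weight, p_temporal,
#'   p_association, bootstrap_score, unknown_ordering.
#' @slot nodeMarginals named numeric of event marginals (may be empty).
#' @slot memberMap named list from node ids to aggregated member ids.
#' @slot params list recording how the model was fitted.
#'
#' @aliases MutationalGraph-class
#' @exportClass MutationalGraph
setClass("MutationalGraph",
  representation(nodes = "character", edges = "data.frame",
                 nodeMarginals = "numeric", memberMap = "list",
                 params = "list")
)

setValidity("MutationalGraph", function(object) {
  msg <- .validGraphEdges(object@nodes, object@edges)
  if (!isTRUE(msg)) return(msg)
  if (nrow(object@edges) > 0L && .hasDirectedCycle(object@edges))
    return("graph contains a directed cycle")
  TRUE
})

.validGraphEdges <- function(nodes, edges) {
  if (anyDuplicated(nodes)) return("node ids must be unique")
  if (!all(c("from", "to") %in% names(edges)))
    return("edges need 'from' and 'to' columns")
  if (nrow(edges) > 0L) {
    if (any(!edges$from %in% nodes) || any(!edges$to %in% nodes))
      return("edge endpoints must be nodes")
    if (any(edges$from == edges$to)) return("self loops not allowed")
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")))
      return("duplicate edges not allowed")
  }
  TRUE
}

.hasDirectedCycle <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")])
  !igraph::is_dag(g)
}
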