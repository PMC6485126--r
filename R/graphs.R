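## Graph containers, accessors and serialisation.

.EDGE_COLS <- c("from", "to", "weight", "p_temporal", "p_association",
                "bootstrap_score", "unknown_ordering")

# normalise an edge table to the canonical column set
.edgeFrame <- function(edges = NULL) {
  base <- data.frame(from = character(), to = character(),
                     weight = numeric(), p_temporal = numeric(),
                     p_association = numeric(), bootstrap_score = numeric(),
                     unknown_ordering = logical(), stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) return(base)
  for (col in .EDGE_COLS)
    if (is.null(edges[[col]]))
      edges[[col]] <- if (col == "unknown_ordering") FALSE else NA_real_
  edges <- edges[, .EDGE_COLS]
  rownames(edges) <- NULL
  edges
}

#' Construct a MutationalGraph
#'
#' Used mostly internally; end users obtain MutationalGraph objects from
#' \code{\link{removeLoops}} and the fitting functions. Acyclicity is
#' enforced on construction.
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with at least \code{from} and \code{to}; optional
#'   \code{weight}, \code{p_temporal}, \code{p_association},
#'   \code{bootstrap_score}, \code{unknown_ordering}.
#' @param nodeMarginals named numeric vector of event marginals.
#' @param memberMap named list of aggregate memberships.
#' @param params provenance list.
#' @return a \linkS4class{MutationalGraph}.
#' @export
mutationalGraph <- function(nodes, edges = NULL, nodeMarginals = numeric(),
                            memberMap = list(), params = list()) {
  new("MutationalGraph", nodes = as.character(nodes),
      edges = .edgeFrame(edges), nodeMarginals = nodeMarginals,
      memberMap = memberMap, params = params)
}

#' @rdname graph-accessors
#' @export
setMethod("graphNodes", "MutationalGraph", function(x) x@nodes)

#' @rdname graph-accessors
#' @export
setMethod("graphEdges", "MutationalGraph", function(x) x@edges)

#' @rdname graph-accessors
#' @export
setMethod("memberMap", "MutationalGraph", function(x) x@memberMap)

#' @rdname graph-accessors
#' @export
setMethod("nodeMarginals", "MutationalGraph", function(x) x@nodeMarginals)

#' @rdname graph-accessors
#' @export
setMethod("graphNodes", "PrimaFacieGraph", function(x) x@nodes)

#' @rdname graph-accessors
#' @export
setMethod("graphEdges", "PrimaFacieGraph", function(x) x@edges)

#' @rdname graph-accessors
#' @export
setMethod("memberMap", "PrimaFacieGraph", function(x) x@memberMap)

#' @rdname graph-accessors
#' @export
setMethod("nodeMarginals", "PrimaFacieGraph", function(x) x@nodeMarginals)

.showGraph <- function(object, what) {
  e <- object@edges
  comp <- .weakComponents(object@nodes, e)
  cat(sprintf("%s: %d nodes, %d edges, %d component(s)\n", what,
              length(object@nodes), nrow(e), length(comp)))
  if (nrow(e) > 0L) {
    shown <- utils::head(e, 10L)
    for (i in seq_len(nrow(shown)))
      cat(sprintf("  %s -> %s (w = %.4g)\n", shown$from[i], shown$to[i],
                  shown$weight[i]))
    if (nrow(e) > 10L) cat(sprintf("  ... %d more edges\n", nrow(e) - 10L))
  }
}

setMethod("show", "MutationalGraph", function(object)
  .showGraph(object, "MutationalGraph"))

setMethod("show", "PrimaFacieGraph", function(object)
  .showGraph(object, "PrimaFacieGraph"))

# weakly connected components as a list of node-id vectors
.weakComponents <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     vertices = data.frame(name = nodes))
  cm <- igraph::components(g, mode = "weak")$membership
  split(names(cm), cm)
}

.asIgraph <- function(nodes, edges) {
  igraph::graph_from_data_frame(edges, vertices = data.frame(name = nodes))
}

## ---- serialisation ------------------------------------------------------

#' Write an inferred graph to disk
#'
#' \code{edge_table} is a TSV with one row per edge and columns
#' (source, target, weight, p_temporal, p_association, bootstrap_score,
#' unknown_ordering), preceded by comment lines listing the nodes and any
#' aggregate memberships, so that \code{\link{readGraphEdgeTable}} restores
#' the graph exactly (weights kept to full precision). \code{dot} renders
#' edges with confidence styling: bootstrap score >= 0.75 drawn bold,
#' unknown-ordering edges (equal marginal frequencies) drawn red and
#' dashed. \code{graphml} delegates to igraph.
#'
#' @param g a \linkS4class{MutationalGraph}.
#' @param path output file.
#' @param format one of \code{"edge_table"}, \code{"dot"}, \code{"graphml"}.
#' @return invisibly, \code{path}.
#' @export
writeGraph <- function(g, path, format = c("edge_table", "dot", "graphml")) {
  if (length(format) == 1L && !format %in% c("edge_table", "dot", "graphml"))
    stop("unknown graph format: ", format)
  format <- match.arg(format)
  e <- graphEdges(g)
  if (format == "edge_table") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nodes: %s", paste(graphNodes(g), collapse = ",")),
               con)
    mm <- memberMap(g)
    for (id in names(mm))
      if (length(mm[[id]]) > 1L)
        writeLines(sprintf("# aggregate: %s = %s", id,
                           paste(mm[[id]], collapse = ",")), con)
    tab <- data.frame(source = e$from, target = e$to,
                      weight = sprintf("%.10g", e$weight),
                      p_temporal = sprintf("%.10g", e$p_temporal),
                      p_association = sprintf("%.10g", e$p_association),
                      bootstrap_score = sprintf("%.10g", e$bootstrap_score),
                      unknown_ordering = e$unknown_ordering,
                      stringsAsFactors = FALSE)
    writeLines(paste(names(tab), collapse = "\t"), con)
    if (nrow(tab) > 0L)
      writeLines(do.call(paste, c(tab, sep = "\t")), con)
  } else if (format == "dot") {
    lines <- c("digraph mutational_graph {", "  node [shape=box];")
    for (v in graphNodes(g))
      lines <- c(lines, sprintf("  \"%s\";", v))
    if (nrow(e) > 0L) {
      for (i in seq_len(nrow(e))) {
        style <- character()
        if (isTRUE(e$unknown_ordering[i]))
          style <- c(style, "color=red", "style=dashed")
        if (!is.na(e$bootstrap_score[i]) && e$bootstrap_score[i] >= 0.75)
          style <- c(style, "penwidth=2")
        lab <- sprintf("label=\"%.3g\"", e$weight[i])
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [%s];", e$from[i],
                                  e$to[i],
                                  paste(c(lab, style), collapse = ", ")))
      }
    }
    writeLines(c(lines, "}"), path)
  } else {
    ig <- .asIgraph(graphNodes(g), graphEdges(g))
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' Read a graph written as an edge table
#'
#' @param path file produced by \code{\link{writeGraph}} with format
#'   \code{"edge_table"}.
#' @return a \linkS4class{MutationalGraph}.
#' @export
readGraphEdgeTable <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  nodesLine <- sub("^# nodes: ?", "", meta[startsWith(meta, "# nodes:")])
  nodes <- if (nzchar(nodesLine)) strsplit(nodesLine, ",")[[1]]
           else character()
  mm <- list()
  for (l in meta[startsWith(meta, "# aggregate:")]) {
    body <- sub("^# aggregate: ?", "", l)
    parts <- strsplit(body, " = ")[[1]]
    mm[[parts[1L]]] <- strsplit(parts[2L], ",")[[1]]
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  edges <- if (nrow(tab) > 0L)
    data.frame(from = as.character(tab$source), to = as.character(tab$target),
               weight = as.numeric(tab$weight),
               p_temporal = as.numeric(tab$p_temporal),
               p_association = as.numeric(tab$p_association),
               bootstrap_score = as.numeric(tab$bootstrap_score),
               unknown_ordering = as.logical(tab$unknown_ordering),
               stringsAsFactors = FALSE)
  else NULL
  mutationalGraph(nodes, edges, memberMap = mm)
}
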