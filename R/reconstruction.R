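## Steps 2-3: render the prima facie graph acyclic, then fit the output
## model with one of four algorithms (Edmonds, Gabow, Chow-Liu, Prim) and
## score models by likelihood.

.ALGORITHMS <- c("edmonds", "gabow", "chow_liu", "prim")

#' Remove loops from a prima facie graph
#'
#' Cycles arise when an edge between two events cannot be unequivocally
#' directed (e.g. small samples giving uncertain bootstrap estimates). The
#' graph is rendered acyclic by iteratively deleting, within each
#' non-trivial strongly connected component (whose edges all lie on some
#' cycle), the least confident edge — confidence being 1 minus the smaller
#' of the edge's two test p-values, with weight and then lexicographic
#' (from, to) order as tie-breaks — until no cycles remain. Edges outside
#' every cycle are never touched.
#'
#' @param g a \linkS4class{PrimaFacieGraph}.
#' @return an acyclic \linkS4class{MutationalGraph} (the no-loop graph).
#' @export
removeLoops <- function(g) {
  e <- graphEdges(g)
  conf <- e$confidence
  if (is.null(conf)) conf <- 1 - pmin(e$p_temporal, e$p_association)
  nodes <- graphNodes(g)
  while (nrow(e) > 0L) {
    ig <- .asIgraph(nodes, e[, c("from", "to")])
    scc <- igraph::components(ig, mode = "strong")
    if (all(scc$csize == 1L)) break
    member <- scc$membership[nodes]
    drop <- integer()
    for (comp in which(scc$csize > 1L)) {
      inComp <- nodes[member == comp]
      cand <- which(e$from %in% inComp & e$to %in% inComp)
      ord <- order(conf[cand], e$weight[cand], e$from[cand], e$to[cand])
      drop <- c(drop, cand[ord[1L]])
    }
    e <- e[-drop, , drop = FALSE]
    conf <- conf[-drop]
  }
  mutationalGraph(nodes, e, nodeMarginals = nodeMarginals(g),
                  memberMap = memberMap(g),
                  params = c(g@params, list(step = "no_loop")))
}

## ---- optimum branching ---------------------------------------------------

# detect a cycle in a parent-pointer map; parent[v] == 0 means none.
# Returns the node indices on one cycle, or NULL.
.findParentCycle <- function(parent, n) {
  mark <- integer(n)                 # 0 new, -1 on current path, 1 done
  for (v in seq_len(n)) {
    if (mark[v] != 0L) next
    path <- integer(0)
    cur <- v
    while (cur != 0L && mark[cur] == 0L) {
      mark[cur] <- -1L
      path <- c(path, cur)
      cur <- parent[cur]
    }
    if (cur != 0L && mark[cur] == -1L)
      return(path[seq.int(match(cur, path), length(path))])
    mark[path] <- 1L
  }
  NULL
}

# best (max-weight) incoming edge per non-root node; ties broken by the
# lexicographic edge id assigned at entry
.bestInEdges <- function(n, edges, root) {
  best <- rep(NA_integer_, n)
  for (v in setdiff(seq_len(n), root)) {
    cand <- which(edges$to == v)
    if (length(cand) == 0L) next
    cand <- cand[order(-edges$w[cand], edges$id[cand])]
    best[v] <- cand[1L]
  }
  best
}

# contract one cycle: returns the rebuilt edge list, the id of the
# contracted super-node, plus bookkeeping needed for expansion
.contractCycle <- function(n, edges, root, best, cycle) {
  inC <- rep(FALSE, n); inC[cycle] <- TRUE
  newId <- integer(n)
  k <- 0L
  for (v in seq_len(n)) if (!inC[v]) { k <- k + 1L; newId[v] <- k }
  cid <- k + 1L
  newId[cycle] <- cid
  keep <- !(inC[edges$from] & inC[edges$to])
  ne <- edges[keep, , drop = FALSE]
  entering <- inC[ne$to]
  wAdj <- ne$w
  wAdj[entering] <- ne$w[entering] - edges$w[best[ne$to[entering]]]
  rec <- list(
    enterIds = ne$id[entering],            # original ids of edges into C
    enterTarget = ne$to[entering],         # cycle node each would attach to
    cycleEdgeIds = edges$id[best[cycle]],  # chosen edges around the cycle
    bestIdByNode = setNames(edges$id[best[cycle]], cycle))
  list(n = cid, root = newId[root],
       edges = data.frame(from = newId[ne$from], to = newId[ne$to],
                          w = wAdj, id = ne$id), rec = rec)
}

# recursive Chu-Liu/Edmonds maximum arborescence; every non-root node is
# assumed to have at least one incoming edge (guaranteed by the virtual
# root). Returns the ids of selected edges.
.chuLiuEdmonds <- function(n, edges, root) {
  best <- .bestInEdges(n, edges, root)
  parent <- rep(0L, n)
  sel <- !is.na(best)
  parent[sel] <- edges$from[best[sel]]
  cycle <- .findParentCycle(parent, n)
  if (is.null(cycle)) return(edges$id[best[sel]])
  ctr <- .contractCycle(n, edges, root, best, cycle)
  sub <- .chuLiuEdmonds(ctr$n, ctr$edges, ctr$root)
  .expandCycle(sub, ctr$rec)
}

.expandCycle <- function(chosen, rec) {
  enter <- intersect(chosen, rec$enterIds)
  vIn <- rec$enterTarget[match(enter[1L], rec$enterIds)]
  dropId <- rec$bestIdByNode[[as.character(vIn)]]
  c(chosen, setdiff(rec$cycleEdgeIds, dropId))
}

# iterative optimum branching: same contraction principle executed with an
# explicit loop and a stack of contraction records, expanded in reverse
.iterativeBranching <- function(n, edges, root) {
  stack <- list()
  repeat {
    best <- .bestInEdges(n, edges, root)
    parent <- rep(0L, n)
    sel <- !is.na(best)
    parent[sel] <- edges$from[best[sel]]
    cycle <- .findParentCycle(parent, n)
    if (is.null(cycle)) {
      chosen <- edges$id[best[sel]]
      break
    }
    ctr <- .contractCycle(n, edges, root, best, cycle)
    stack[[length(stack) + 1L]] <- ctr$rec
    n <- ctr$n; edges <- ctr$edges; root <- ctr$root
  }
  for (rec in rev(stack)) chosen <- .expandCycle(chosen, rec)
  chosen
}

# shared front end: set up integer ids, virtual root below all real
# weights, run the requested engine, return row indices of kept edges.
# Works on any directed edge table (cyclic inputs are handled by the
# contraction engines themselves).
.branchingFit <- function(g, engine) {
  .optimumBranchingRows(graphNodes(g), graphEdges(g), engine)
}

.optimumBranchingRows <- function(nodes, e, engine) {
  if (nrow(e) == 0L) return(integer())
  ord <- order(e$from, e$to)
  e <- e[ord, , drop = FALSE]
  w <- e$weight
  finite <- is.finite(w)
  floorW <- if (any(finite)) min(w[finite]) else 0
  w[!finite] <- floorW - 1                 # -Inf sentinel: minimal weight
  nv <- length(nodes)
  virt <- min(w, 0) - 1
  edges <- data.frame(
    from = c(match(e$from, nodes), rep(nv + 1L, nv)),
    to = c(match(e$to, nodes), seq_len(nv)),
    w = c(w, rep(virt, nv)),
    id = c(seq_len(nrow(e)), -seq_len(nv)))
  chosen <- engine(nv + 1L, edges, nv + 1L)
  ord[sort(chosen[chosen > 0L])]
}

.branchingGraph <- function(g, keepRows, algorithm) {
  e <- graphEdges(g)[keepRows, , drop = FALSE]
  mutationalGraph(graphNodes(g), e, nodeMarginals = nodeMarginals(g),
                  memberMap = memberMap(g),
                  params = c(g@params, list(algorithm = algorithm)))
}

#' Fit the output model by Edmonds' optimum branching
#'
#' Computes, over each weakly connected component of the no-loop graph, the
#' spanning arborescence of maximum total edge weight (Chu-Liu/Edmonds with
#' a virtual root attached to every node at a weight strictly below all
#' real edges, so root placement is decided by the data). Every node ends
#' with in-degree at most 1; k weakly connected components yield k trees.
#'
#' @param g an acyclic weighted \linkS4class{MutationalGraph} from
#'   \code{\link{removeLoops}}.
#' @return a tree/forest \linkS4class{MutationalGraph}.
#' @export
fitEdmonds <- function(g) {
  .branchingGraph(g, .branchingFit(g, .chuLiuEdmonds), "edmonds")
}

#' Fit the output model by iterative optimum branching
#'
#' An optimum-branching variant that performs cycle contraction iteratively
#' with an explicit contraction stack rather than recursion; by optimality
#' its total weight equals \code{\link{fitEdmonds}}' on every input.
#'
#' @inheritParams fitEdmonds
#' @return a tree/forest \linkS4class{MutationalGraph}.
#' @export
fitGabow <- function(g) {
  .branchingGraph(g, .branchingFit(g, .iterativeBranching), "gabow")
}

## ---- undirected skeleton fits -------------------------------------------

# maximum-weight spanning forest of an undirected weighted skeleton;
# pairs: data.frame(u, v, w). Returns kept row indices.
.maxSpanningForest <- function(nodes, pairs) {
  if (nrow(pairs) == 0L) return(integer())
  w <- pairs$w
  finite <- is.finite(w)
  w[!finite] <- (if (any(finite)) min(w[finite]) else 0) - 1
  ig <- igraph::graph_from_data_frame(
    data.frame(from = pairs$u, to = pairs$v, rowid = seq_len(nrow(pairs))),
    directed = FALSE, vertices = data.frame(name = nodes))
  mst <- igraph::mst(ig, weights = -w)
  sort(igraph::edge_attr(mst, "rowid"))
}

# collapse a directed edge table to its undirected skeleton, keeping for
# each unordered pair the maximum weight and the p-values of the better
# directed edge
.undirectedSkeleton <- function(e) {
  if (nrow(e) == 0L)
    return(data.frame(u = character(), v = character(), w = numeric(),
                      p_temporal = numeric(), p_association = numeric()))
  u <- pmin(e$from, e$to); v <- pmax(e$from, e$to)
  key <- paste(u, v, sep = "\r")
  ord <- order(key, -ifelse(is.finite(e$weight), e$weight, -Inf))
  first <- !duplicated(key[ord])
  idx <- ord[first]
  data.frame(u = u[idx], v = v[idx], w = e$weight[idx],
             p_temporal = e$p_temporal[idx],
             p_association = e$p_association[idx],
             stringsAsFactors = FALSE)
}

# direct skeleton edges by temporal priority: the endpoint with the higher
# marginal frequency points at the lower one; equal marginals cannot be
# ordered and are flagged, with lexicographic direction for determinism.
# Directing along this total order cannot create cycles, but it can create
# confluences (a node both of whose tree neighbours have higher marginals).
.directByMarginals <- function(sk, marg) {
  if (nrow(sk) == 0L)
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), p_temporal = numeric(),
                      p_association = numeric(),
                      unknown_ordering = logical()))
  mu <- marg[sk$u]; mv <- marg[sk$v]
  fwd <- mu > mv | (mu == mv)        # u -> v; lexicographic on ties
  data.frame(from = ifelse(fwd, sk$u, sk$v), to = ifelse(fwd, sk$v, sk$u),
             weight = sk$w, p_temporal = sk$p_temporal,
             p_association = sk$p_association,
             unknown_ordering = mu == mv, stringsAsFactors = FALSE)
}

#' Fit the output model by Chow-Liu tree factorisation
#'
#' Per weakly connected component, computes the undirected spanning tree of
#' maximum total mutual information over the no-loop graph's skeleton (the
#' Chow-Liu factorisation of the joint distribution restricted to
#' candidate edges), then directs each edge by temporal priority: the
#' event with the higher marginal frequency points at the lower one. When
#' both tree neighbours of a node have higher marginals the node receives
#' two parents (a confluence) and the output is a DAG; equal-marginal
#' pairs are flagged \code{unknown_ordering}.
#'
#' @param d the NA-free (aggregated) \linkS4class{GenotypeMatrix} the graph
#'   was inferred from; mutual information is re-estimated from it.
#' @param g the no-loop \linkS4class{MutationalGraph}.
#' @param noise a \linkS4class{NoiseRates} for probability correction.
#' @return a \linkS4class{MutationalGraph}, possibly with confluences.
#' @export
fitChowLiu <- function(d, g, noise = noiseRates(0, 0)) {
  stats <- pairStatistics(d, noise)
  sk <- .undirectedSkeleton(graphEdges(g))
  if (nrow(sk) > 0L) sk$w <- stats$mi[cbind(sk$u, sk$v)]
  keep <- .maxSpanningForest(graphNodes(g), sk)
  marg <- nodeMarginals(g)
  if (!length(marg)) marg <- stats$pX
  e <- .directByMarginals(sk[keep, , drop = FALSE], marg)
  mutationalGraph(graphNodes(g), e, nodeMarginals = marg,
                  memberMap = memberMap(g),
                  params = c(g@params, list(algorithm = "chow_liu")))
}

#' Fit the output model by Prim's maximum spanning tree
#'
#' Per weakly connected component, greedily accretes the maximum-weight
#' undirected spanning tree of the no-loop graph's skeleton using the
#' graph's own edge weights, then directs edges by the same
#' marginal-frequency temporal-priority rule as \code{\link{fitChowLiu}}.
#'
#' @inheritParams fitEdmonds
#' @return a \linkS4class{MutationalGraph}, possibly with confluences.
#' @export
fitPrim <- function(g) {
  sk <- .undirectedSkeleton(graphEdges(g))
  keep <- .maxSpanningForest(graphNodes(g), sk)
  e <- .directByMarginals(sk[keep, , drop = FALSE], nodeMarginals(g))
  mutationalGraph(graphNodes(g), e, nodeMarginals = nodeMarginals(g),
                  memberMap = memberMap(g),
                  params = c(g@params, list(algorithm = "prim")))
}

## ---- likelihood ----------------------------------------------------------

#' Log-likelihood of data under a graph-factorised model
#'
#' Factorises the joint distribution along the graph: root nodes contribute
#' Bernoulli marginals at their empirical frequency, every other node a
#' conditional Bernoulli given its parents' configuration, with all
#' parameters estimated from \code{d} itself (maximum likelihood;
#' \code{pseudocount} > 0 adds smoothing to each conditional cell for
#' scoring a graph against data it was not estimated from).
#'
#' @param g a \linkS4class{MutationalGraph} whose nodes are columns of
#'   \code{d} (aggregate nodes are resolved through \code{memberMap}).
#' @param d an NA-free \linkS4class{GenotypeMatrix}.
#' @param pseudocount added to each conditional count (default 0).
#' @return the log-likelihood (natural log).
#' @export
modelLikelihood <- function(g, d, pseudocount = 0) {
  v <- genotypes(d)
  if (anyNA(v)) stop("dataset contains NA; impute first")
  cols <- colnames(v)
  colFor <- function(node) {
    if (node %in% cols) return(node)
    mm <- memberMap(g)[[node]]
    hit <- mm[mm %in% cols]
    if (length(hit)) return(hit[1L])
    stop("graph node not found in dataset: ", node)
  }
  bern <- function(n1, n0) {
    p1 <- (n1 + pseudocount) / (n1 + n0 + 2 * pseudocount)
    t1 <- if (n1 > 0L) n1 * log(p1) else 0
    t0 <- if (n0 > 0L) n0 * log(1 - p1) else 0
    t1 + t0
  }
  e <- graphEdges(g)
  ll <- 0
  for (node in graphNodes(g)) {
    y <- v[, colFor(node)]
    parents <- e$from[e$to == node]
    if (length(parents) == 0L) {
      ll <- ll + bern(sum(y), length(y) - sum(y))
    } else {
      pv <- v[, vapply(parents, colFor, character(1)), drop = FALSE]
      cfg <- apply(pv, 1L, paste, collapse = "")
      for (k in unique(cfg)) {
        yk <- y[cfg == k]
        ll <- ll + bern(sum(yk), length(yk) - sum(yk))
      }
    }
  }
  ll
}

## ---- pipeline ------------------------------------------------------------

#' Infer a mutational graph from a binary genotype matrix
#'
#' The full three-step pipeline: (1) merge events with identical profiles
#' and screen all ordered pairs with Suppes' temporal-priority and
#' association conditions via bootstrap Mann-Whitney tests, building the
#' weighted prima facie graph; (2) remove loops by deleting the least
#' confident cycle edges; (3) fit the output model with the chosen
#' algorithm. Datasets containing NAs are dispatched to
#' \code{\link{fitWithMissing}} (EM multiple imputation + likelihood model
#' selection).
#'
#' @param d a \linkS4class{GenotypeMatrix}.
#' @param algorithm one of \code{"edmonds"}, \code{"gabow"},
#'   \code{"chow_liu"}, \code{"prim"}.
#' @param B bootstrap resamples for the Suppes tests.
#' @param alpha significance level for edge inclusion.
#' @param noise a priori \linkS4class{NoiseRates}.
#' @param weight prima facie edge weight: \code{"pmi"} or \code{"mi"}.
#' @param aggregate merge identical-profile events first (default TRUE).
#' @param nImputations imputed datasets when \code{d} has missing entries.
#' @return a \linkS4class{MutationalGraph}; edges between events with equal
#'   observed marginal frequencies are flagged \code{unknown_ordering}.
#' @examples
#' set.seed(1)
#' sim <- simulateDataset(n = 6, m = 100)
#' g <- inferGraph(sim$dataset, algorithm = "edmonds", B = 25)
#' graphEdges(g)
#' @export
inferGraph <- function(d, algorithm = c("edmonds", "gabow", "chow_liu",
                                        "prim"),
                       B = 100L, alpha = 0.05, noise = noiseRates(0, 0),
                       weight = c("pmi", "mi"), aggregate = TRUE,
                       nImputations = 100L) {
  algorithm <- match.arg(algorithm)
  weight <- match.arg(weight)
  if (anyNA(genotypes(d)))
    return(fitWithMissing(d, algorithm = algorithm, B = B, alpha = alpha,
                          noise = noise, weight = weight,
                          aggregate = aggregate,
                          nImputations = nImputations))
  da <- if (aggregate) aggregateEvents(d) else d
  pf <- primaFacieGraph(da, B = B, alpha = alpha, noise = noise,
                        weight = weight)
  gnl <- removeLoops(pf)
  fit <- switch(algorithm,
                edmonds = fitEdmonds(gnl),
                gabow = fitGabow(gnl),
                chow_liu = fitChowLiu(da, gnl, noise),
                prim = fitPrim(gnl))
  e <- graphEdges(fit)
  if (nrow(e) > 0L) {
    obs <- colMeans(genotypes(da))
    eq <- obs[e$from] == obs[e$to]
    e$unknown_ordering <- ifelse(is.na(e$unknown_ordering), eq,
                                 e$unknown_ordering | eq)
    fit@edges <- e
  }
  fit
}
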