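# Independent oracles and small fixture builders used across the suite.

# Brute-force maximum branching with a virtual root: every node picks one
# incoming edge or attaches to the virtual root at weight `virt`; the
# acyclic assignment maximising total weight (real edges at their weight,
# virtual attachments at virt) is found by exhaustive enumeration.
bruteForceBranchingWeight <- function(nodes, edges, virt) {
  n <- length(nodes)
  choicesFor <- function(v) c(0L, which(edges$to == nodes[v]))
  best <- -Inf
  recurse <- function(v, parent, total) {
    if (v > n) {
      # acyclicity check on parent pointers
      for (s in seq_len(n)) {
        seen <- logical(n); cur <- s
        while (parent[cur] != 0L) {
          if (seen[cur]) return(invisible(NULL))
          seen[cur] <- TRUE
          cur <- parent[cur]
        }
      }
      best <<- max(best, total)
      return(invisible(NULL))
    }
    for (ch in choicesFor(v)) {
      if (ch == 0L) {
        parent[v] <- 0L
        recurse(v + 1L, parent, total + virt)
      } else {
        parent[v] <- match(edges$from[ch], nodes)
        recurse(v + 1L, parent, total + edges$w[ch])
      }
    }
  }
  recurse(1L, integer(n), 0)
  best
}

# total weight fitEdmonds' objective assigns to a fitted graph, using the
# same virtual-root cost for every tree root
branchingObjective <- function(g, virt) {
  e <- graphEdges(g)
  sum(e$weight) + (length(graphNodes(g)) - nrow(e)) * virt
}

# all labelled spanning trees on n nodes via Pruefer decoding
allSpanningTrees <- function(n) {
  if (n == 1L) return(list(matrix(integer(), 0, 2)))
  if (n == 2L) return(list(matrix(c(1L, 2L), 1, 2)))
  seqs <- do.call(expand.grid, rep(list(seq_len(n)), n - 2L))
  lapply(seq_len(nrow(seqs)), function(i) {
    pruefer <- as.integer(seqs[i, ])
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    edges <- matrix(integer(), 0, 2)
    for (v in pruefer) {
      leaf <- min(which(degree == 1L))
      edges <- rbind(edges, c(leaf, v))
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    rbind(edges, last)
  })
}

# maximum-total-weight spanning tree weight by exhaustive enumeration;
# wmat: symmetric weight matrix
exhaustiveMaxSpanningTreeWeight <- function(wmat) {
  n <- nrow(wmat)
  max(vapply(allSpanningTrees(n), function(e)
    sum(wmat[e]), numeric(1)))
}

# random weighted digraph for branching-equivalence trials
randomWeightedDag <- function(nNodes, pEdge = 0.5, acyclic = FALSE) {
  nodes <- letters[seq_len(nNodes)]
  rows <- list()
  for (i in seq_len(nNodes)) {
    for (j in seq_len(nNodes)) {
      if (i == j) next
      if (acyclic && i > j) next
      if (runif(1) < pEdge)
        rows[[length(rows) + 1L]] <- data.frame(
          from = nodes[i], to = nodes[j], weight = runif(1, -1, 1),
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else NULL
  list(nodes = nodes, edges = edges)
}

# dataset with y strictly nested in x: p(x) = 0.6, p(y) = 0.3, y => x
nestedPairData <- function(m = 100L) {
  x <- c(rep(1L, round(0.6 * m)), rep(0L, m - round(0.6 * m)))
  y <- c(rep(1L, round(0.3 * m)), rep(0L, m - round(0.3 * m)))
  GenotypeMatrix(matrix(c(x, y), ncol = 2,
                        dimnames = list(sprintf("s%03d", seq_len(m)),
                                        c("x", "y"))))
}

# deterministic chain topology with strictly decreasing marginals
chainTopology <- function(n = 5L, rootProb = 0.95, childProb = 0.8) {
  ids <- sprintf("c%02d", seq_len(n))
  parent <- setNames(c(NA_character_, ids[-n]), ids)
  topology(parent, setNames(c(rootProb, rep(childProb, n - 1L)), ids))
}
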