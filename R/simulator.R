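## Synthetic-data generator: ground-truthed single-cell and multi-region
## binary datasets with asymmetric noise, missing entries and confounders.

#' Construct a Topology
#'
#' @param parent named character vector child -> parent, NA for roots; the
#'   names define the node set.
#' @param nodeProb named numeric activation probabilities (defaults to 1).
#' @return a \linkS4class{Topology}.
#' @examples
#' topology(c(a = NA, b = "a", c = "a"), c(a = 1, b = 0.5, c = 0.5))
#' @export
topology <- function(parent, nodeProb = NULL) {
  nodes <- names(parent)
  if (is.null(nodeProb)) nodeProb <- setNames(rep(1, length(nodes)), nodes)
  new("Topology", nodes = nodes,
      parent = setNames(as.character(parent), nodes),
      nodeProb = nodeProb[nodes])
}

#' @rdname topology-accessors
#' @export
setMethod("rootNodes", "Topology",
          function(x) x@nodes[is.na(x@parent[x@nodes])])

#' @rdname topology-accessors
#' @export
setMethod("parentMap", "Topology", function(x) x@parent)

#' @rdname topology-accessors
#' @export
setMethod("nodeProb", "Topology", function(x) x@nodeProb)

#' @rdname topology-accessors
#' @export
setMethod("trueEdges", "Topology", function(x) {
  keep <- !is.na(x@parent)
  data.frame(from = unname(x@parent[keep]), to = names(x@parent)[keep],
             stringsAsFactors = FALSE)
})

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d nodes, %d root(s): %s\n", length(object@nodes),
              length(rootNodes(object)),
              paste(rootNodes(object), collapse = ", ")))
})

# children lists, in node order for deterministic traversal
.childrenMap <- function(t) {
  p <- parentMap(t)
  lapply(setNames(t@nodes, t@nodes),
         function(v) names(p)[!is.na(p) & p == v])
}

#' Sample a random generative tree or forest
#'
#' Draws a random recursive forest: the first q nodes are roots, every later
#' node attaches to a uniformly chosen earlier node. Activation
#' probabilities are drawn independently and uniformly on
#' [\code{probMin}, \code{probMax}] per node: for a root this is the
#' marginal probability the founding alteration is present in a sampled
#' cell, for an internal node the probability the alteration is acquired
#' given the parental lineage reaches it. The default lower bound 0.5 keeps
#' every event at callable prevalence — an event annotated in the input is
#' there because it was detected, and sorted single-cell samples carry the
#' founder alteration in most cells — so that edge recovery is limited by
#' sample size and noise rather than by events that effectively never
#' occur.
#'
#' @param n number of nodes.
#' @param q number of roots (disconnected trees), 1 <= q <= n.
#' @param probMin,probMax bounds of the activation-probability draw.
#' @param prefix node id prefix.
#' @return a \linkS4class{Topology} with exactly q parentless nodes.
#' @export
sampleTopology <- function(n, q = 1L, probMin = 0.5, probMax = 1,
                           prefix = "e") {
  if (q > n || q < 1L) stop("need 1 <= q <= n")
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  parent <- setNames(rep(NA_character_, n), ids)
  if (n > q)
    for (i in seq.int(q + 1L, n))
      parent[i] <- ids[sample.int(i - 1L, 1L)]
  topology(parent, setNames(runif(n, probMin, probMax), ids))
}

#' Sample single-cell genotypes from a topology
#'
#' Recursive generative process for exclusive branching lineages under the
#' infinite-sites assumption: each root is present with its activation
#' probability; below a node that is present, one child is selected
#' uniformly at random and becomes present with its own activation
#' probability, all other children (and their subtrees) are absent; the
#' recursion stops when a 0 is sampled or a leaf is reached. Hence a child
#' can be 1 only when its parent is 1, and among the children of any node
#' at most one is 1 per cell.
#'
#' @param t a \linkS4class{Topology}.
#' @param m number of cells to sample.
#' @return a single-cell \linkS4class{GenotypeMatrix} (m x n, no NA).
#' @export
sampleSCGenotypes <- function(t, m) {
  nodes <- t@nodes
  kids <- .childrenMap(t)
  prob <- nodeProb(t)
  roots <- rootNodes(t)
  v <- matrix(0L, nrow = m, ncol = length(nodes),
              dimnames = list(sprintf("cell%04d", seq_len(m)), nodes))
  descend <- function(row, v0) {
    repeat {
      ch <- kids[[v0]]
      if (length(ch) == 0L) return(row)
      pick <- ch[[sample.int(length(ch), 1L)]]
      if (runif(1) >= prob[[pick]]) return(row)
      row[[pick]] <- 1L
      v0 <- pick
    }
  }
  for (i in seq_len(m)) {
    row <- setNames(integer(length(nodes)), nodes)
    for (r in roots) {
      if (runif(1) < prob[[r]]) {
        row[[r]] <- 1L
        row <- descend(row, r)
      }
    }
    v[i, ] <- row
  }
  GenotypeMatrix(v, dataKind = "single_cell")
}

#' Pool single-cell genotypes into multi-region bulk profiles
#'
#' Emulates bulk sequencing of spatially separated regions, each an
#' admixture of tumour lineages: for every region a pool of single-cell
#' genotypes is sampled from the topology and an event is called present
#' when the fraction of pooled cells carrying it exceeds the detection
#' threshold.
#'
#' @param t a \linkS4class{Topology}.
#' @param mRegions number of bulk regions (rows of the output).
#' @param cellsPerRegion cells pooled per region.
#' @param threshold presence-calling fraction in (0, 1); event set to 1 iff
#'   (carrying cells) / cellsPerRegion > threshold.
#' @return a multi-region \linkS4class{GenotypeMatrix}.
#' @export
poolBulk <- function(t, mRegions, cellsPerRegion = 10L, threshold = 0.05) {
  if (cellsPerRegion < 1L) stop("cellsPerRegion must be >= 1")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  v <- matrix(0L, nrow = mRegions, ncol = length(t@nodes),
              dimnames = list(sprintf("region%02d", seq_len(mRegions)),
                              t@nodes))
  for (i in seq_len(mRegions)) {
    cells <- genotypes(sampleSCGenotypes(t, cellsPerRegion))
    v[i, ] <- as.integer(colMeans(cells) > threshold)
  }
  GenotypeMatrix(v, dataKind = "multi_region")
}

#' Perturb genotypes with asymmetric calling noise
#'
#' Each observed 0 flips to 1 independently with probability fp (sequencing
#' artefacts) and each 1 flips to 0 with probability fn (allelic dropout;
#' typically fp << fn in single-cell data). Missing entries are untouched.
#'
#' @param d a \linkS4class{GenotypeMatrix}.
#' @param noise a \linkS4class{NoiseRates}.
#' @return the perturbed \linkS4class{GenotypeMatrix}.
#' @export
injectNoise <- function(d, noise) {
  v <- genotypes(d)
  flip <- matrix(runif(length(v)), nrow(v))
  out <- v
  out[!is.na(v) & v == 0L & flip < fpRate(noise)] <- 1L
  out[!is.na(v) & v == 1L & flip < fnRate(noise)] <- 0L
  initialize(d, values = out)
}

#' Knock out entries uniformly at random
#'
#' Sets exactly floor(r * m * n) entries, chosen uniformly without
#' replacement over all cells of the matrix, to NA, so the realised
#' missing-data fraction matches r exactly (up to flooring).
#'
#' @param d a \linkS4class{GenotypeMatrix}.
#' @param r missing-data fraction in [0, 1).
#' @return a \linkS4class{GenotypeMatrix} with NAs added.
#' @export
injectMissing <- function(d, r) {
  if (r < 0 || r >= 1) stop("r must be in [0, 1)")
  v <- genotypes(d)
  k <- floor(r * length(v))
  if (k > 0L) v[sample.int(length(v), k)] <- NA_integer_
  initialize(d, values = v)
}

#' Append confounder events unrelated to the progression
#'
#' Each confounder column is an i.i.d. Bernoulli sample whose bias is drawn
#' uniformly from the multiset of existing event marginals (NA-excluded
#' means), emulating miscalled or progression-unrelated alterations whose
#' frequency looks plausible.
#'
#' @param d a \linkS4class{GenotypeMatrix} with at least one event.
#' @param count number of columns to add; default round(n * 0.1), at least
#'   1.
#' @param prefix id prefix for the new columns.
#' @return a \linkS4class{GenotypeMatrix} with \code{count} extra events.
#' @export
addConfounders <- function(d, count = max(1L, round(0.1 * nEvents(d))),
                           prefix = "conf") {
  if (count == 0L) return(d)
  v <- genotypes(d)
  marg <- colMeans(v, na.rm = TRUE)
  extra <- vapply(seq_len(count), function(i) {
    bias <- marg[[sample.int(length(marg), 1L)]]
    rbinom(nrow(v), 1L, bias)
  }, integer(nrow(v)))
  extra <- matrix(as.integer(extra), nrow = nrow(v),
                  dimnames = list(rownames(v),
                                  sprintf("%s%02d", prefix,
                                          seq_len(count))))
  GenotypeMatrix(cbind(v, extra), dataKind = dataKind(d))
}

#' One-call simulation of a ground-truthed dataset
#'
#' Samples a topology and a dataset under the stated study conditions:
#' exclusive-branching single-cell genotypes (or pooled bulk regions),
#' then asymmetric noise, uniform missing entries, and confounder columns,
#' in that order.
#'
#' @param n number of true events.
#' @param q number of roots.
#' @param m number of samples (cells or regions).
#' @param dataKind \code{"single_cell"} or \code{"multi_region"}.
#' @param noise a \linkS4class{NoiseRates}.
#' @param missingRate uniform missing-entry fraction in [0, 1).
#' @param nConfounders confounder columns to append (0 = none).
#' @param cellsPerRegion,threshold bulk pooling parameters (multi-region
#'   only).
#' @param topology optionally, a fixed \linkS4class{Topology} to sample
#'   from instead of drawing one.
#' @return list with elements \code{topology} and \code{dataset}.
#' @export
simulateDataset <- function(n = 11L, q = 1L, m = 50L,
                            dataKind = c("single_cell", "multi_region"),
                            noise = noiseRates(0, 0), missingRate = 0,
                            nConfounders = 0L, cellsPerRegion = 10L,
                            threshold = 0.05, topology = NULL) {
  dataKind <- match.arg(dataKind)
  t <- if (is.null(topology)) sampleTopology(n, q) else topology
  d <- if (dataKind == "single_cell") sampleSCGenotypes(t, m)
       else poolBulk(t, m, cellsPerRegion, threshold)
  if (fpRate(noise) > 0 || fnRate(noise) > 0) d <- injectNoise(d, noise)
  if (nConfounders > 0L) d <- addConfounders(d, nConfounders)
  if (missingRate > 0) d <- injectMissing(d, missingRate)
  list(topology = t, dataset = d)
}

#' Write / read a topology as a plain-text table
#'
#' TSV with columns \code{node}, \code{parent} (empty for roots) and
#' \code{prob}; round-trips through \code{readTopology}.
#'
#' @param t a \linkS4class{Topology}.
#' @param path file path.
#' @return \code{writeTopology}: invisibly, \code{path};
#'   \code{readTopology}: a \linkS4class{Topology}.
#' @export
writeTopology <- function(t, path) {
  p <- parentMap(t)
  tab <- data.frame(node = names(p), parent = ifelse(is.na(p), "", p),
                    prob = sprintf("%.10g", nodeProb(t)[names(p)]),
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTopology
#' @export
readTopology <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                    na.strings = NULL)
  parent <- setNames(ifelse(tab$parent == "", NA_character_, tab$parent),
                     tab$node)
  topology(parent, setNames(as.numeric(tab$prob), tab$node))
}
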