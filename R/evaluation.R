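## Ground-truth comparison metrics and the simulation-study harness:
## scenario grids, noise-robustness scan and missing-data scan.

#' Edge-level sensitivity and specificity against a ground truth
#'
#' Scores an inferred model against the direct parent -> child edges of the
#' generative topology, over all ordered pairs of distinct nodes. Aggregate
#' nodes are first expanded so each member inherits the aggregate's
#' attachments; inferred nodes absent from the truth (e.g. confounders)
#' count as nodes with no true edges. TP are true edges recovered, FN true
#' edges missed, FP inferred non-true edges, TN the remaining pairs;
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), with an empty
#' denominator scoring 1.
#'
#' @param truth a \linkS4class{Topology}.
#' @param inferred a \linkS4class{MutationalGraph}.
#' @return named numeric vector with elements \code{sensitivity} and
#'   \code{specificity}.
#' @export
sensitivitySpecificity <- function(truth, inferred) {
  mm <- memberMap(inferred)
  members <- function(id) {
    m <- mm[[id]]
    if (is.null(m)) id else m
  }
  infNodes <- unique(unlist(lapply(graphNodes(inferred), members)))
  tNodes <- truth@nodes
  if (!all(tNodes %in% infNodes))
    stop("inferred graph is missing true nodes: ",
         paste(setdiff(tNodes, infNodes), collapse = ", "))
  nodes <- union(tNodes, infNodes)
  te <- trueEdges(truth)
  trueKeys <- paste(te$from, te$to, sep = "\r")
  e <- graphEdges(inferred)
  infKeys <- character()
  for (i in seq_len(nrow(e)))
    infKeys <- c(infKeys, as.vector(outer(members(e$from[i]),
                                          members(e$to[i]), paste,
                                          sep = "\r")))
  infKeys <- unique(infKeys)
  nPairs <- length(nodes) * (length(nodes) - 1L)
  tp <- sum(infKeys %in% trueKeys)
  fp <- length(infKeys) - tp
  fn <- length(trueKeys) - tp
  tn <- nPairs - tp - fp - fn
  c(sensitivity = if (tp + fn == 0L) 1 else tp / (tp + fn),
    specificity = if (tn + fp == 0L) 1 else tn / (tn + fp))
}

.performanceRecord <- function(scenario, algorithm, n, m, q, noise, r,
                               metrics, seed = NA_integer_) {
  data.frame(scenario = scenario, algorithm = algorithm, n = n, m = m,
             q = q, fp = fpRate(noise), fn = fnRate(noise),
             missing_rate = r, sensitivity = metrics[["sensitivity"]],
             specificity = metrics[["specificity"]], seed = seed,
             stringsAsFactors = FALSE)
}

#' Run a simulation-study grid
#'
#' For every row of the configuration grid, simulates \code{nDatasets}
#' independent ground-truthed datasets (fresh random topology each, unless
#' one is fixed), infers a model with each requested algorithm and scores
#' it against the generative truth. Covers the three study scenarios:
#' single-rooted trees (q = 1), confounded data (nConfounders > 0) and
#' polyclonal forests (q > 1).
#'
#' @param grid data.frame with columns among \code{n}, \code{q}, \code{m},
#'   \code{fp}, \code{fn}, \code{missing_rate}, \code{n_confounders},
#'   \code{data_kind}; missing columns get defaults (n = 11, q = 1, m = 50,
#'   noise-free, no missing data, no confounders, single_cell).
#' @param algorithms character vector of fitting algorithms.
#' @param nDatasets independent datasets per grid row.
#' @param B,alpha,weight inference controls (see \code{\link{inferGraph}}).
#' @param nImputations imputations when missing data are simulated.
#' @param topology optional fixed \linkS4class{Topology} reused for every
#'   dataset.
#' @param scenario label stored in the records.
#' @return data.frame of performance records, one row per (grid row,
#'   dataset, algorithm).
#' @export
runScenario <- function(grid, algorithms = "edmonds", nDatasets = 100L,
                        B = 100L, alpha = 0.05, weight = "pmi",
                        nImputations = 100L, topology = NULL,
                        scenario = "scenario") {
  defaults <- list(n = 11L, q = 1L, m = 50L, fp = 0, fn = 0,
                   missing_rate = 0, n_confounders = 0L,
                   data_kind = "single_cell")
  for (col in names(defaults))
    if (is.null(grid[[col]])) grid[[col]] <- defaults[[col]]
  recs <- list()
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    noise <- noiseRates(gr$fp, gr$fn)
    for (j in seq_len(nDatasets)) {
      sim <- simulateDataset(n = gr$n, q = gr$q, m = gr$m,
                             dataKind = gr$data_kind, noise = noise,
                             missingRate = gr$missing_rate,
                             nConfounders = gr$n_confounders,
                             topology = topology)
      for (algo in algorithms) {
        fit <- inferGraph(sim$dataset, algorithm = algo, B = B,
                          alpha = alpha, noise = noise, weight = weight,
                          nImputations = nImputations)
        recs[[length(recs) + 1L]] <- .performanceRecord(
          scenario, algo, gr$n, gr$m, gr$q, noise, gr$missing_rate,
          sensitivitySpecificity(sim$topology, fit))
      }
    }
  }
  do.call(rbind, recs)
}

#' Scan robustness to misspecified input noise rates
#'
#' Refits one dataset (generated under known true rates) across a grid of
#' input false-positive/false-negative rates handed to the algorithm, and
#' scores each fit against the truth; used to check that mild rate
#' misspecification leaves performance essentially unchanged. The default
#' grids are fp = (3,4,5,6,7)e-3 and fn = (3,4,5,6,7)e-2 (25 combinations).
#'
#' @param d the observed \linkS4class{GenotypeMatrix}.
#' @param truth the generative \linkS4class{Topology}.
#' @param algorithm fitting algorithm.
#' @param fpGrid,fnGrid input rates to scan.
#' @param B,alpha,weight inference controls.
#' @return data.frame of performance records, one per (fp, fn) cell.
#' @export
noiseRobustnessScan <- function(d, truth, algorithm = "gabow",
                                fpGrid = c(3, 4, 5, 6, 7) * 1e-3,
                                fnGrid = c(3, 4, 5, 6, 7) * 1e-2,
                                B = 100L, alpha = 0.05, weight = "pmi") {
  recs <- list()
  for (fp in fpGrid) {
    for (fn in fnGrid) {
      noise <- noiseRates(fp, fn)
      fit <- inferGraph(d, algorithm = algorithm, B = B, alpha = alpha,
                        noise = noise, weight = weight)
      recs[[length(recs) + 1L]] <- .performanceRecord(
        "noise_scan", algorithm, nEvents(d), nSamples(d),
        length(rootNodes(truth)), noise, 0,
        sensitivitySpecificity(truth, fit))
    }
  }
  do.call(rbind, recs)
}

#' Missing-data robustness experiment
#'
#' Benchmarks imputation-based fitting on datasets from a fixed topology:
#' \code{nDatasets} base datasets are simulated (noise arms assigned
#' round-robin from \code{noiseOptions}), each is degraded to every
#' missing-data fraction in \code{rGrid}, fitted with
#' \code{\link{fitWithMissing}}, and scored against the truth. The
#' full-scale design uses 20 datasets (half noise-free, half with fp =
#' 0.005, fn = 0.05), r = 0, 0.1, 0.2, 0.3, 0.4 and 100 imputations,
#' yielding 100 records.
#'
#' @param truth the generative \linkS4class{Topology}.
#' @param algorithm fitting algorithm.
#' @param rGrid missing-data fractions.
#' @param nDatasets base datasets.
#' @param noiseOptions list of \linkS4class{NoiseRates}, assigned
#'   round-robin across base datasets.
#' @param m cells per dataset.
#' @param nImputations imputations per fit with missing data.
#' @param B,alpha,weight inference controls.
#' @return data.frame of performance records, one per (dataset, r).
#' @export
missingDataScan <- function(truth, algorithm = "edmonds",
                            rGrid = c(0, 0.1, 0.2, 0.3, 0.4),
                            nDatasets = 20L,
                            noiseOptions = list(noiseRates(0, 0),
                                                noiseRates(0.005, 0.05)),
                            m = 75L, nImputations = 100L, B = 100L,
                            alpha = 0.05, weight = "pmi") {
  recs <- list()
  for (j in seq_len(nDatasets)) {
    noise <- noiseOptions[[(j - 1L) %% length(noiseOptions) + 1L]]
    base <- sampleSCGenotypes(truth, m)
    if (fpRate(noise) > 0 || fnRate(noise) > 0)
      base <- injectNoise(base, noise)
    for (r in rGrid) {
      d <- if (r > 0) injectMissing(base, r) else base
      fit <- fitWithMissing(d, algorithm = algorithm, B = B, alpha = alpha,
                            noise = noise, weight = weight,
                            nImputations = nImputations)
      recs[[length(recs) + 1L]] <- .performanceRecord(
        "missing_data", algorithm, nEvents(base), m,
        length(rootNodes(truth)), noise, r,
        sensitivitySpecificity(truth, fit))
    }
  }
  do.call(rbind, recs)
}
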