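## Missing-data handling: EM-based multiple imputation and
## likelihood-based model selection across imputed datasets.

#' Impute missing entries by EM multiple imputation
#'
#' Fits an independent-Bernoulli model per event by
#' expectation-maximisation over the missing-data likelihood (E-step:
#' expected value of each NA under the current marginal; M-step: update the
#' marginal including those expectations), iterating to convergence, then
#' draws each imputed dataset by sampling every NA from its converged
#' Bernoulli expectation. Observed entries are never modified. Under this
#' model the converged marginal equals the observed-entry frequency, and
#' dependence between events is restored downstream by fitting each
#' imputed dataset and selecting by the graph-factorised likelihood.
#'
#' @param d a \linkS4class{GenotypeMatrix}, possibly with NA entries.
#' @param nImputations number of complete datasets to draw.
#' @param tol EM convergence threshold on the largest absolute marginal
#'   change.
#' @param maxIter EM iteration cap.
#' @return list of \code{nImputations} NA-free
#'   \linkS4class{GenotypeMatrix} objects.
#' @export
emImpute <- function(d, nImputations = 100L, tol = 1e-6, maxIter = 100L) {
  v <- genotypes(d)
  if (!anyNA(v))
    return(replicate(nImputations, d, simplify = FALSE))
  obs <- !is.na(v)
  globalMean <- mean(v, na.rm = TRUE)
  if (is.nan(globalMean)) globalMean <- 0.5
  allNA <- colSums(obs) == 0L
  if (any(allNA))
    warning("column(s) entirely NA, filled from the global marginal: ",
            paste(colnames(v)[allNA], collapse = ", "))
  # EM on the product-Bernoulli missing-data likelihood
  mu <- ifelse(allNA, globalMean,
               colMeans(ifelse(obs, v, globalMean), na.rm = TRUE))
  for (it in seq_len(maxIter)) {
    ev <- v
    ev[!obs] <- rep(mu, each = nrow(v))[!obs]
    muNew <- colMeans(ev)
    muNew[allNA] <- globalMean
    if (max(abs(muNew - mu)) < tol) { mu <- muNew; break }
    mu <- muNew
  }
  naIdx <- which(!obs, arr.ind = TRUE)
  p <- mu[naIdx[, 2L]]
  lapply(seq_len(nImputations), function(i) {
    out <- v
    out[naIdx] <- rbinom(nrow(naIdx), 1L, p)
    initialize(d, values = out)
  })
}

#' Infer a model from data with missing entries
#'
#' Generates \code{nImputations} complete datasets with
#' \code{\link{emImpute}}, runs the full inference pipeline on each, and
#' returns the fitted model of maximal graph-factorised log-likelihood
#' (each model scored on its own imputed dataset). Ties are broken by total
#' edge weight, then by the lexicographic edge set, for determinism.
#'
#' @inheritParams inferGraph
#' @param tol,maxIter EM controls, passed to \code{\link{emImpute}}.
#' @return the selected \linkS4class{MutationalGraph}.
#' @export
fitWithMissing <- function(d, algorithm = c("edmonds", "gabow", "chow_liu",
                                            "prim"),
                           B = 100L, alpha = 0.05, noise = noiseRates(0, 0),
                           weight = c("pmi", "mi"), aggregate = TRUE,
                           nImputations = 100L, tol = 1e-6,
                           maxIter = 100L) {
  algorithm <- match.arg(algorithm)
  weight <- match.arg(weight)
  if (!anyNA(genotypes(d)))
    return(inferGraph(d, algorithm = algorithm, B = B, alpha = alpha,
                      noise = noise, weight = weight,
                      aggregate = aggregate))
  imps <- emImpute(d, nImputations = nImputations, tol = tol,
                   maxIter = maxIter)
  best <- NULL
  edgeKey <- function(g) {
    e <- graphEdges(g)
    paste(sort(paste(e$from, e$to, sep = ">")), collapse = ";")
  }
  for (di in imps) {
    g <- inferGraph(di, algorithm = algorithm, B = B, alpha = alpha,
                    noise = noise, weight = weight, aggregate = aggregate)
    ll <- modelLikelihood(g, if (aggregate) aggregateEvents(di) else di)
    w <- sum(graphEdges(g)$weight[is.finite(graphEdges(g)$weight)])
    cand <- list(g = g, ll = ll, w = w, key = edgeKey(g))
    if (is.null(best) ||
        cand$ll > best$ll ||
        (cand$ll == best$ll && cand$w > best$w) ||
        (cand$ll == best$ll && cand$w == best$w && cand$key < best$key))
      best <- cand
  }
  best$g
}
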