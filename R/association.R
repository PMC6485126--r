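## Step 1: probability estimation with noise correction, Suppes'
## temporal-priority and association conditions assessed by bootstrap +
## one-tailed Mann-Whitney tests, and construction of the prima facie graph.

# invert the misclassification channel on a marginal:
# p_obs = p_true (1 - fn) + (1 - p_true) fp
.correctMarginal <- function(p, fp, fn) {
  pmin(pmax((p - fp) / (1 - fp - fn), 0), 1)
}

# invert the channel on 2x2 joints, elementwise over matrices o11..o00;
# negative cells are clamped to 0 and the table renormalised
.correctJoint <- function(o11, o10, o01, o00, fp, fn) {
  det <- 1 - fp - fn
  i0 <- c(1 - fn, -fn) / det   # weights of obs (0,1) for true = 0
  i1 <- c(-fp, 1 - fp) / det   # weights of obs (0,1) for true = 1
  cell <- function(a, b) {
    a[1] * b[1] * o00 + a[1] * b[2] * o01 + a[2] * b[1] * o10 +
      a[2] * b[2] * o11
  }
  t11 <- pmax(cell(i1, i1), 0); t10 <- pmax(cell(i1, i0), 0)
  t01 <- pmax(cell(i0, i1), 0); t00 <- pmax(cell(i0, i0), 0)
  tot <- t11 + t10 + t01 + t00
  list(t11 = t11 / tot, t10 = t10 / tot, t01 = t01 / tot, t00 = t00 / tot)
}

#' Mutual information and pointwise mutual information (bits)
#'
#' For binary events x and y with joint co-occurrence probability
#' \code{p11 = p(x=1, y=1)} and marginals \code{px}, \code{py}:
#' \code{mutualInformation} is the expected log2 ratio of joint to product
#' marginals over the four cells (with 0 log 0 = 0);
#' \code{pointwiseMutualInformation} is log2(p11 / (px py)) of the
#' co-occurrence cell, -Inf when p11 = 0 (ranked below every finite
#' weight).
#'
#' @param p11 joint probability p(x=1, y=1); vectorised.
#' @param px,py marginal probabilities.
#' @return information in bits.
#' @examples
#' mutualInformation(0.5, 0.5, 0.5)          # x == y: 1 bit
#' pointwiseMutualInformation(0.3, 0.6, 0.3) # ~0.737 bits
#' @export
mutualInformation <- function(p11, px, py) {
  p10 <- pmax(px - p11, 0); p01 <- pmax(py - p11, 0)
  p00 <- pmax(1 - px - py + p11, 0)
  term <- function(pab, pa, pb) {
    out <- pab * log2(pab / (pa * pb))
    out[!is.finite(out) | pab <= 0] <- 0
    out
  }
  term(p11, px, py) + term(p10, px, 1 - py) + term(p01, 1 - px, py) +
    term(p00, 1 - px, 1 - py)
}

#' @rdname mutualInformation
#' @export
pointwiseMutualInformation <- function(p11, px, py) {
  out <- log2(p11 / (px * py))
  out[p11 <= 0] <- -Inf
  out
}

#' Empirical (noise-corrected) pair statistics
#'
#' Estimates marginal, joint and conditional probabilities for all ordered
#' event pairs from an NA-free genotype matrix. When nonzero noise rates
#' are supplied, observed frequencies are corrected by inverting the
#' misclassification model (marginals linearly; joints by 2x2 matrix
#' inversion), clamping to [0, 1] and renormalising.
#'
#' @param d an NA-free \linkS4class{GenotypeMatrix}.
#' @param noise a \linkS4class{NoiseRates}; zero rates leave frequencies
#'   untouched.
#' @return list with named vector \code{pX} and n x n matrices \code{p11}
#'   (joint), \code{pYgX}, \code{pYgNX} (conditionals of the column event
#'   given the row event), \code{mi} and \code{pmi} (bits). Diagonals are
#'   NA.
#' @export
pairStatistics <- function(d, noise = noiseRates(0, 0)) {
  v <- genotypes(d)
  if (anyNA(v)) stop("dataset contains NA; impute first (see emImpute)")
  fp <- fpRate(noise); fn <- fnRate(noise)
  m <- nrow(v); n <- ncol(v)
  n1 <- colSums(v)
  c11 <- crossprod(v)
  o11 <- c11 / m
  o10 <- (matrix(n1, n, n) - c11) / m          # x = 1, y = 0
  o01 <- (matrix(n1, n, n, byrow = TRUE) - c11) / m
  o00 <- 1 - o11 - o10 - o01
  ct <- .correctJoint(o11, o10, o01, o00, fp, fn)
  pX <- .correctMarginal(n1 / m, fp, fn)
  pxj <- ct$t11 + ct$t10                       # x marginal from joint table
  pYgX <- ct$t11 / pxj
  pYgNX <- ct$t01 / (1 - pxj)
  pyj <- ct$t11 + ct$t01
  mi <- mutualInformation(ct$t11, pxj, pyj)
  pmi <- pointwiseMutualInformation(ct$t11, pxj, pyj)
  diag(ct$t11) <- diag(pYgX) <- diag(pYgNX) <- diag(mi) <- diag(pmi) <- NA
  ev <- colnames(v)
  dimnames(ct$t11) <- dimnames(pYgX) <- dimnames(pYgNX) <-
    dimnames(mi) <- dimnames(pmi) <- list(ev, ev)
  list(pX = setNames(pX, ev), p11 = ct$t11, pYgX = pYgX, pYgNX = pYgNX,
       mi = mi, pmi = pmi)
}

# one-tailed Mann-Whitney comparison of paired bootstrap statistics: the
# U statistic of the B within-replicate differences against zero (midrank
# ties) estimates the bootstrap probability that the condition holds under
# resampling; the reported p-value is its complement. Pairing within
# replicates is what the shared row-resample design is for: it preserves
# the dependence between the two statistics (for nested events the
# difference is non-negative in every resample). A fully tied comparison
# gives 0.5: no evidence of ordering.
.mwGreater <- function(a, b) {
  if (length(a) == 0L) return(1)
  d <- a - b
  U <- sum(d > 0) + 0.5 * sum(d == 0)
  1 - U / length(d)
}

# shared bootstrap machinery: B row resamples, reused across all pairs.
# Returns corrected per-replicate marginals and conditionals plus the
# validity mask for the association test (conditioning event must be
# non-degenerate in the replicate).
.bootstrapPairArrays <- function(v, noise, B) {
  fp <- fpRate(noise); fn <- fnRate(noise)
  m <- nrow(v); n <- ncol(v)
  P <- matrix(NA_real_, B, n)
  CYX <- array(NA_real_, c(n, n, B))
  CYNX <- array(NA_real_, c(n, n, B))
  valid <- matrix(FALSE, n, B)
  for (b in seq_len(B)) {
    M <- v[sample.int(m, m, replace = TRUE), , drop = FALSE]
    n1 <- colSums(M)
    c11 <- crossprod(M)
    o11 <- c11 / m
    o10 <- (matrix(n1, n, n) - c11) / m
    o01 <- (matrix(n1, n, n, byrow = TRUE) - c11) / m
    ct <- .correctJoint(o11, o10, o01, 1 - o11 - o10 - o01, fp, fn)
    P[b, ] <- .correctMarginal(n1 / m, fp, fn)
    pxj <- ct$t11 + ct$t10
    CYX[, , b] <- ct$t11 / pxj
    CYNX[, , b] <- ct$t01 / (1 - pxj)
    valid[, b] <- n1 > 0L & n1 < m
  }
  list(P = P, CYX = CYX, CYNX = CYNX, valid = valid)
}

#' Test Suppes' conditions for one ordered event pair
#'
#' Assesses whether x is a plausible temporal predecessor of y: the
#' temporal-priority condition p(x) > p(y) and the association condition
#' p(y|x) > p(y|not x) are each evaluated on B nonparametric bootstrap
#' resamples of the samples, and the two replicate distributions compared
#' by the one-tailed Mann-Whitney U statistic of the within-replicate
#' differences against zero (midrank ties): the reported p-value is
#' 1 - U/B, the bootstrap probability that the condition is violated under
#' resampling. Replicates in
#' which x is unobserved or ubiquitous leave the conditionals undefined and
#' are dropped from the association test; if more than half are dropped the
#' pair is rejected outright.
#'
#' @param d an NA-free \linkS4class{GenotypeMatrix}.
#' @param x,y event ids, distinct.
#' @param B number of bootstrap resamples.
#' @param alpha significance level applied to both tests.
#' @param noise a \linkS4class{NoiseRates} used to correct probabilities
#'   before each evaluation.
#' @return list with \code{p_temporal}, \code{p_association},
#'   \code{passed} (both p-values below alpha), and
#'   \code{dropped_fraction}.
#' @export
suppesTest <- function(d, x, y, B = 100L, alpha = 0.05,
                       noise = noiseRates(0, 0)) {
  if (identical(x, y)) stop("x and y must differ")
  v <- genotypes(d)[, c(x, y), drop = FALSE]
  if (anyNA(v)) stop("dataset contains NA; impute first")
  bs <- .bootstrapPairArrays(v, noise, B)
  .suppesFromArrays(bs, 1L, 2L, alpha)
}

.suppesFromArrays <- function(bs, ix, iy, alpha) {
  pt <- .mwGreater(bs$P[, ix], bs$P[, iy])
  vb <- bs$valid[ix, ] & is.finite(bs$CYX[ix, iy, ]) &
    is.finite(bs$CYNX[ix, iy, ])
  droppedFraction <- mean(!vb)
  if (droppedFraction > 0.5) {
    pa <- 1
  } else {
    pa <- .mwGreater(bs$CYX[ix, iy, vb], bs$CYNX[ix, iy, vb])
  }
  list(p_temporal = pt, p_association = pa,
       passed = pt < alpha && pa < alpha,
       dropped_fraction = droppedFraction)
}

#' Merge events with identical observed profiles
#'
#' Events occurring in exactly the same samples carry indistinguishable
#' statistical signal for temporal ordering and are merged into a single
#' aggregate event before inference; NA is compared as a distinct symbol.
#' The aggregate's id and label are the concatenation of the member labels
#' and the membership is retained in \code{memberMap} for output
#' labelling.
#'
#' @param d a \linkS4class{GenotypeMatrix}.
#' @return a \linkS4class{GenotypeMatrix} with one column per distinct
#'   profile; \code{memberMap(d)} maps every remaining column to its
#'   members (length > 1 for aggregates).
#' @export
aggregateEvents <- function(d) {
  v <- genotypes(d)
  key <- apply(v, 2L, function(col)
    paste(ifelse(is.na(col), "N", col), collapse = ""))
  groups <- split(colnames(v), factor(key, levels = unique(key)))
  ids <- unname(vapply(groups, function(g) paste(g, collapse = ","),
                       character(1)))
  out <- v[, vapply(groups, `[`, character(1), 1L), drop = FALSE]
  colnames(out) <- ids
  info <- eventInfo(d)
  kinds <- vapply(groups, function(g) {
    k <- unique(info$kind[match(g, info$id)])
    if (length(k) == 1L) k else "other"
  }, character(1))
  labels <- vapply(groups, function(g)
    paste(info$label[match(g, info$id)], collapse = ","), character(1))
  events <- data.frame(id = ids, label = unname(labels),
                       kind = unname(kinds), stringsAsFactors = FALSE)
  GenotypeMatrix(out, events = events, dataKind = dataKind(d),
                 memberMap = setNames(unname(groups), ids))
}

#' Build the prima facie graph of candidate temporal orderings
#'
#' Runs \code{\link{suppesTest}} for every ordered pair of events, sharing
#' one set of B bootstrap row-resamples across all pairs, and keeps the
#' edge x -> y whenever both conditions are significant at level alpha.
#' Edges are weighted by mutual information or pointwise mutual
#' information (bits) computed from the (noise-corrected) full-data
#' probabilities, and carry a confidence score 1 - min(p-values) used for
#' loop removal. The result may be cyclic and/or disconnected.
#'
#' @param d an NA-free, typically aggregated, \linkS4class{GenotypeMatrix}.
#' @param B bootstrap resamples.
#' @param alpha significance level.
#' @param noise a \linkS4class{NoiseRates}.
#' @param weight edge weight kind: \code{"pmi"} (default) or \code{"mi"}.
#' @return a \linkS4class{PrimaFacieGraph}.
#' @export
primaFacieGraph <- function(d, B = 100L, alpha = 0.05,
                            noise = noiseRates(0, 0),
                            weight = c("pmi", "mi")) {
  weight <- match.arg(weight)
  v <- genotypes(d)
  if (anyNA(v)) stop("dataset contains NA; impute first (see emImpute)")
  n <- ncol(v)
  ev <- colnames(v)
  stats <- pairStatistics(d, noise)
  W <- if (weight == "pmi") stats$pmi else stats$mi
  edges <- NULL
  if (n > 1L) {
    bs <- .bootstrapPairArrays(v, noise, B)
    rows <- list()
    for (ix in seq_len(n)) {
      for (iy in seq_len(n)) {
        if (ix == iy) next
        res <- .suppesFromArrays(bs, ix, iy, alpha)
        if (res$passed)
          rows[[length(rows) + 1L]] <- data.frame(
            from = ev[ix], to = ev[iy], weight = W[ix, iy],
            p_temporal = res$p_temporal, p_association = res$p_association,
            confidence = 1 - min(res$p_temporal, res$p_association),
            stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), p_temporal = numeric(),
                        p_association = numeric(), confidence = numeric(),
                        stringsAsFactors = FALSE)
  new("PrimaFacieGraph", nodes = ev, edges = edges,
      nodeMarginals = stats$pX, memberMap = memberMap(d),
      params = list(alpha = alpha, B = B, weight = weight,
                    fp = fpRate(noise), fn = fnRate(noise)))
}
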