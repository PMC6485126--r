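## Post-hoc confidence: nonparametric bootstrap edge scores and the
## hypergeometric overlap test used to annotate output models.

#' A posteriori bootstrap confidence scores for inferred edges
#'
#' Refits the full pipeline on \code{nBoot} datasets obtained by resampling
#' samples (rows) with replacement at full size, and scores every directed
#' edge by the fraction of refits that contain it. Aggregate nodes are
#' expanded to their member events before counting, so scores are
#' comparable across refits whose aggregation differs.
#'
#' @inheritParams inferGraph
#' @param nBoot number of bootstrap refits.
#' @return data.frame with columns \code{from}, \code{to}, \code{score}
#'   (in [0, 1]), one row per edge observed in any refit.
#' @seealso \code{\link{annotateBootstrapScores}}
#' @export
bootstrapEdgeScores <- function(d, algorithm = c("edmonds", "gabow",
                                                 "chow_liu", "prim"),
                                nBoot = 100L, B = 100L, alpha = 0.05,
                                noise = noiseRates(0, 0),
                                weight = c("pmi", "mi"),
                                nImputations = 100L) {
  algorithm <- match.arg(algorithm)
  weight <- match.arg(weight)
  v <- genotypes(d)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(nBoot)) {
    vb <- v[sample.int(nrow(v), nrow(v), replace = TRUE), , drop = FALSE]
    rownames(vb) <- sprintf("bs%05d", seq_len(nrow(vb)))
    db <- initialize(d, values = vb)
    g <- inferGraph(db, algorithm = algorithm, B = B, alpha = alpha,
                    noise = noise, weight = weight,
                    nImputations = nImputations)
    for (key in .expandedEdgeKeys(g)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) +
        1L
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L)
    return(data.frame(from = character(), to = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                    to = vapply(parts, `[`, character(1), 2L),
                    score = vapply(keys, function(k) counts[[k]] / nBoot,
                                   numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$from, out$to), ]
}

# directed edges of g expanded through aggregate membership
.expandedEdgeKeys <- function(g) {
  e <- graphEdges(g)
  if (nrow(e) == 0L) return(character())
  mm <- memberMap(g)
  members <- function(id) {
    m <- mm[[id]]
    if (is.null(m)) id else m
  }
  keys <- character()
  for (i in seq_len(nrow(e)))
    keys <- c(keys, as.vector(outer(members(e$from[i]), members(e$to[i]),
                                    paste, sep = "\r")))
  unique(keys)
}

#' Attach bootstrap scores to a fitted graph
#'
#' Fills the \code{bootstrap_score} edge column of \code{g} from a score
#' table produced by \code{\link{bootstrapEdgeScores}}; edges never seen in
#' a refit score 0.
#'
#' @param g a \linkS4class{MutationalGraph}.
#' @param scores data.frame from \code{\link{bootstrapEdgeScores}}.
#' @return \code{g} with \code{bootstrap_score} populated.
#' @export
annotateBootstrapScores <- function(g, scores) {
  e <- graphEdges(g)
  if (nrow(e) == 0L) return(g)
  mm <- memberMap(g)
  members <- function(id) {
    m <- mm[[id]]
    if (is.null(m)) id else m
  }
  lut <- setNames(scores$score, paste(scores$from, scores$to, sep = "\r"))
  e$bootstrap_score <- vapply(seq_len(nrow(e)), function(i) {
    keys <- as.vector(outer(members(e$from[i]), members(e$to[i]), paste,
                            sep = "\r"))
    s <- lut[keys]
    s[is.na(s)] <- 0
    mean(s)
  }, numeric(1))
  g@edges <- e
  g
}

#' Hypergeometric test of sample overlap between two events
#'
#' Upper-tail p-value for observing at least the actual co-occurrence
#' count when the samples carrying y are drawn without replacement into the
#' samples carrying x: population m, draws = count(x = 1), successes =
#' count(y = 1). Small values indicate the two events co-occur more than
#' chance placement allows; the test is exchangeable in x and y.
#'
#' @param d a \linkS4class{GenotypeMatrix} with NA-free columns x and y.
#' @param x,y event ids.
#' @return the p-value; degenerate columns (all 0 or all 1) return 1 with a
#'   warning since overlap carries no information.
#' @export
hypergeometricOverlapTest <- function(d, x, y) {
  v <- genotypes(d)[, c(x, y)]
  if (anyNA(v)) stop("columns contain NA")
  m <- nrow(v)
  nx <- sum(v[, 1L]); ny <- sum(v[, 2L])
  if (nx %in% c(0L, m) || ny %in% c(0L, m)) {
    warning("degenerate column (all 0 or all 1): overlap uninformative")
    return(1)
  }
  k <- sum(v[, 1L] == 1L & v[, 2L] == 1L)
  phyper(k - 1L, ny, m - ny, nx, lower.tail = FALSE)
}
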