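#' Construct a GenotypeMatrix
#'
#' @param values matrix over \{0, 1, NA\}; rows are samples, columns events.
#'   Row/column names are used as sample/event ids when present; default ids
#'   \code{s1..sm} / \code{e1..en} are assigned otherwise.
#' @param events optional data.frame with columns \code{id}, \code{label},
#'   \code{kind}; defaults to labels equal to ids and kind
#'   \code{"mutation"}.
#' @param dataKind \code{"single_cell"} (default) or \code{"multi_region"}.
#' @param memberMap named list mapping event ids to original member ids
#'   (used by \code{\link{aggregateEvents}}); defaults to empty.
#'
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' m <- matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("s1","s2"), c("a","b")))
#' GenotypeMatrix(m)
#' @export
GenotypeMatrix <- function(values, events = NULL,
                           dataKind = c("single_cell", "multi_region"),
                           memberMap = list()) {
  dataKind <- match.arg(dataKind)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("e", seq_len(ncol(values)))
  if (is.null(events))
    events <- data.frame(id = colnames(values), label = colnames(values),
                         kind = "mutation", stringsAsFactors = FALSE)
  new("GenotypeMatrix", values = values, events = events,
      dataKind = dataKind, memberMap = memberMap)
}

#' @rdname GenotypeMatrix
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@values)

#' @rdname GenotypeMatrix
#' @export
setMethod("sampleNames", "GenotypeMatrix", function(x) rownames(x@values))

#' @rdname GenotypeMatrix
#' @export
setMethod("eventNames", "GenotypeMatrix", function(x) colnames(x@values))

#' @rdname GenotypeMatrix
#' @export
setMethod("eventInfo", "GenotypeMatrix", function(x) x@events)

#' @rdname GenotypeMatrix
#' @export
setMethod("dataKind", "GenotypeMatrix", function(x) x@dataKind)

#' @rdname GenotypeMatrix
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@values))

#' @rdname GenotypeMatrix
#' @export
setMethod("nEvents", "GenotypeMatrix", function(x) ncol(x@values))

#' @rdname graph-accessors
#' @export
setMethod("memberMap", "GenotypeMatrix", function(x) x@memberMap)

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@values
  cat(sprintf("GenotypeMatrix: %d samples x %d events [%s]\n",
              nrow(v), ncol(v), object@dataKind))
  nas <- sum(is.na(v))
  cat(sprintf("  1s: %d | 0s: %d | NA: %d (%.1f%%)\n",
              sum(v == 1L, na.rm = TRUE), sum(v == 0L, na.rm = TRUE),
              nas, 100 * nas / length(v)))
  if (length(object@memberMap))
    cat(sprintf("  aggregate events: %d\n",
                sum(lengths(object@memberMap) > 1L)))
})

#' Construct NoiseRates
#'
#' @param fp false-positive rate (0 observed as 1) in [0, 1).
#' @param fn false-negative rate (1 observed as 0, e.g. allelic dropout)
#'   in [0, 1); fp + fn must be < 1.
#' @return a \linkS4class{NoiseRates}.
#' @examples noiseRates(0.005, 0.05)
#' @export
noiseRates <- function(fp = 0, fn = 0) new("NoiseRates", fp = fp, fn = fn)

#' @rdname NoiseRates
#' @export
setMethod("fpRate", "NoiseRates", function(x) x@fp)

#' @rdname NoiseRates
#' @export
setMethod("fnRate", "NoiseRates", function(x) x@fn)

setMethod("show", "NoiseRates", function(object)
  cat(sprintf("NoiseRates: fp = %g, fn = %g\n", object@fp, object@fn)))

## ---- I/O --------------------------------------------------------------

#' Read a binary genotype matrix from delimited text
#'
#' Expects a header row of event ids and a first column of sample ids;
#' remaining cells must be the literal tokens 0, 1 or the NA symbol. No
#' thresholding or binarisation is applied: calling presence/absence from
#' read counts is the caller's responsibility.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param na string representing missing entries (default "NA").
#' @param transpose set TRUE when the file stores events on rows and
#'   samples on columns.
#' @param dataKind passed to \code{\link{GenotypeMatrix}}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @seealso \code{\link{writeGenotypeMatrix}}
#' @export
readGenotypeMatrix <- function(path, sep = "\t", na = "NA",
                               transpose = FALSE,
                               dataKind = c("single_cell", "multi_region")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                    check.names = FALSE, colClasses = "character",
                    comment.char = "", quote = "")
  m <- as.matrix(tab)
  if (transpose) m <- t(m)
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  out[m == "0"] <- 0L
  out[m == "1"] <- 1L
  bad <- which(is.na(out) & m != na, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary token '%s' at sample '%s', event '%s'",
                 m[bad[1L, 1L], bad[1L, 2L]],
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  GenotypeMatrix(out, dataKind = match.arg(dataKind))
}

#' Write a genotype matrix as delimited text
#'
#' @param d a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @param sep field delimiter.
#' @param na string used for missing entries.
#' @return invisibly, \code{path}.
#' @export
writeGenotypeMatrix <- function(d, path, sep = "\t", na = "NA") {
  v <- genotypes(d)
  tab <- cbind(sample = rownames(v), as.data.frame(v, check.names = FALSE))
  write.table(tab, path, sep = sep, na = na, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Report data-quality findings on a genotype matrix
#'
#' Report-only screening ahead of inference: flags events never observed
#' (all-zero columns), always observed (all-one columns: no ordering signal
#' relative to anything), groups of events with identical observed profiles
#' (candidates for aggregation), per-event missing-data fractions, and
#' samples with no observed entry at all.
#'
#' @param d a \linkS4class{GenotypeMatrix}.
#' @param naWarn flag events whose NA fraction is at or above this value.
#' @return data.frame with columns \code{finding}, \code{item},
#'   \code{detail}, \code{value}; zero rows when nothing is flagged.
#' @export
validateDataset <- function(d, naWarn = 0.2) {
  v <- genotypes(d)
  out <- list()
  add <- function(finding, item, detail, value = NA_real_)
    out[[length(out) + 1L]] <<- data.frame(finding = finding, item = item,
                                           detail = detail, value = value,
                                           stringsAsFactors = FALSE)
  zeros <- colnames(v)[colSums(v == 1L, na.rm = TRUE) == 0L]
  for (e in zeros) add("all_zero", e, "event never observed")
  ones <- colnames(v)[colSums(v != 1L, na.rm = TRUE) == 0L]
  for (e in ones) add("all_one", e, "event observed in every sample")
  key <- apply(v, 2L, function(col) paste(ifelse(is.na(col), "N", col),
                                          collapse = ""))
  for (k in unique(key[duplicated(key)])) {
    grp <- colnames(v)[key == k]
    add("duplicate_profile", paste(grp, collapse = ","),
        sprintf("duplicate profile {%s}", paste(grp, collapse = ",")))
  }
  naFrac <- colMeans(is.na(v))
  for (e in colnames(v)[naFrac >= naWarn & naFrac > 0])
    add("high_missing", e, "high missing-data fraction", naFrac[[e]])
  allNA <- rownames(v)[rowSums(!is.na(v)) == 0L]
  for (s in allNA) add("all_na_sample", s, "sample has no observed entry")
  if (length(out)) do.call(rbind, out)
  else data.frame(finding = character(), item = character(),
                  detail = character(), value = numeric(),
                  stringsAsFactors = FALSE)
}
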