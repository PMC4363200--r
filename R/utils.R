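## Low-level sequence utilities shared by the models and the decoders.
## DNA is held internally as integer codes: A=1, C=2, G=3, T=4, N (and any
## other IUPAC ambiguity character) = 0.

.CODE_LETTERS <- c("A", "C", "G", "T")

#' Encode a DNA string as integer codes
#'
#' @param x a single character string over the DNA alphabet (case-insensitive).
#' @return integer vector with A=1, C=2, G=3, T=4 and anything else 0 (treated
#'   as N by all scoring code).
#' @keywords internal
encodeDNA <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  map <- integer(256)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("a")] <- 1L
  map[utf8ToInt("C")] <- 2L; map[utf8ToInt("c")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("g")] <- 3L
  map[utf8ToInt("T")] <- 4L; map[utf8ToInt("t")] <- 4L
  raw <- utf8ToInt(x)
  out <- integer(length(raw))
  ok <- raw >= 1L & raw <= 256L
  out[ok] <- map[raw[ok]]
  out
}

#' @keywords internal
decodeDNA <- function(codes) {
  out <- rep("N", length(codes))
  ok <- codes >= 1L & codes <= 4L
  out[ok] <- .CODE_LETTERS[codes[ok]]
  paste(out, collapse = "")
}

#' Reverse complement of an encoded sequence
#' @keywords internal
revcompCodes <- function(codes) {
  comp <- c(4L, 3L, 2L, 1L)
  out <- integer(length(codes))
  ok <- codes >= 1L & codes <= 4L
  out[ok] <- comp[codes[ok]]
  rev(out)
}

#' @keywords internal
revcompDNA <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Stop codons in encoded form (TAA, TAG, TGA) and as strings.
.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @keywords internal
isStopCodon <- function(codes, at) {
  if (at + 2L > length(codes)) return(FALSE)
  c1 <- codes[at]; c2 <- codes[at + 1L]; c3 <- codes[at + 2L]
  (c1 == 4L && c2 == 1L && (c3 == 1L || c3 == 3L)) ||
    (c1 == 4L && c2 == 3L && c3 == 1L)
}

#' Vector of logicals: does a stop codon start at each position?
#' @keywords internal
stopCodonStarts <- function(codes) {
  L <- length(codes)
  out <- logical(L)
  if (L < 3L) return(out)
  i <- seq_len(L - 2L)
  c1 <- codes[i]; c2 <- codes[i + 1L]; c3 <- codes[i + 2L]
  out[i] <- (c1 == 4L & c2 == 1L & (c3 == 1L | c3 == 3L)) |
    (c1 == 4L & c2 == 3L & c3 == 1L)
  out
}

## A very negative but finite log-probability standing in for -Inf so that
## cumulative-sum emission tricks stay NaN-free.  Anything below .NEG_GUARD
## is treated as "impossible".
.NEG_INF <- -1e30
.NEG_GUARD <- -1e25

#' Contexts as integers.
#'
#' The context of order m preceding position i is bases i-m .. i-1; its index
#' is 1 + sum_{t=1..m} (x[i-t]-1) * 4^(t-1).  Returns 0 where the context
#' window runs off the sequence start or contains an N.
#' @keywords internal
contextIndex <- function(codes, order) {
  L <- length(codes)
  if (order == 0L) return(rep(1L, L))
  idx <- rep(1, L)
  bad <- rep(FALSE, L)
  for (t in seq_len(order)) {
    prev <- c(rep(0L, min(t, L)),
              if (L > t) codes[seq_len(L - t)] else integer(0))
    bad <- bad | prev == 0L
    idx <- idx + (pmax(prev, 1L) - 1L) * 4^(t - 1)
  }
  idx[seq_len(min(order, L))] <- 0
  idx[bad] <- 0
  as.integer(idx)
}

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Merge a sorted set of (start, end) intervals
#' @keywords internal
mergeIntervals <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ks <- start[1]; ke <- end[1]
  outs <- integer(); oute <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ke + 1L) {
      ke <- max(ke, end[i])
    } else {
      outs <- c(outs, ks); oute <- c(oute, ke)
      ks <- start[i]; ke <- end[i]
    }
  }
  data.frame(start = c(outs, ks), end = c(oute, ke))
}
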