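## Weighted array matrices: position-specific k-order models over a fixed
## window, used for the translation-start (Kozak) region and the splice donor,
## acceptor and branch-point signals.

#' Train a weighted array matrix
#'
#' One conditional table per window position; positions closer to the window
#' start than the requested order use a shortened context (backoff within the
#' window).
#'
#' @param windows character vector (or list of integer code vectors) of
#'   aligned windows, all the same length.
#' @param order context order within the window.
#' @param pseudocount additive pseudocount per cell (> 0).
#' @param nFloorLog log-probability floor for ambiguity characters.
#' @param backoffAlpha hierarchical smoothing weight: each order-m conditional
#'   is shrunk towards the order-(m-1) estimate at the same position with this
#'   prior strength (0 = plain pseudocount tables).  Guards against spiky
#'   estimates when the training set cannot populate all contexts.
#' @return a [WeightedArrayMatrix-class].
#' @export
trainWAM <- function(windows, order, pseudocount = 0.01, nFloorLog = log(0.25),
                     backoffAlpha = 0) {
  if (!length(windows)) stop("at least one training window is required")
  if (is.character(windows)) windows <- as.list(windows)
  codes <- lapply(windows, function(s) if (is.character(s)) encodeDNA(s) else as.integer(s))
  lens <- lengths(codes)
  if (length(unique(lens)) != 1L)
    stop("ragged training windows: lengths ", paste(unique(lens), collapse = ", "))
  W <- as.integer(lens[[1]])
  order <- as.integer(order)
  mat <- do.call(rbind, codes)   # n x W

  countsAt <- function(p, m) {
    ctx <- rep(1, nrow(mat))
    bad <- rep(FALSE, nrow(mat))
    if (m > 0L) for (t in seq_len(m)) {
      prev <- mat[, p - t]
      bad <- bad | prev == 0L
      ctx <- ctx + (pmax(prev, 1L) - 1L) * 4^(t - 1)
    }
    base <- mat[, p]
    ok <- !bad & base > 0L
    cm <- matrix(0, nrow = 4^m, ncol = 4L)
    if (any(ok)) {
      flat <- (ctx[ok] - 1L) * 4L + base[ok]
      cm <- matrix(tabulate(flat, nbins = 4^m * 4L), nrow = 4^m, ncol = 4L,
                   byrow = TRUE)
    }
    cm
  }
  positionTables <- vector("list", W)
  for (p in seq_len(W)) {
    mtop <- min(order, p - 1L)
    prevTab <- NULL
    for (m in 0:mtop) {
      cm <- countsAt(p, m)
      prior <- if (is.null(prevTab)) matrix(0.25, nrow = 1L, ncol = 4L)
               else prevTab
      ## order-m context c maps to order-(m-1) context (c-1) %% 4^(m-1) + 1
      ## (the most recent m-1 bases are the low-order digits of the index)
      pr <- if (m == 0L) prior
            else prior[((seq_len(4^m) - 1L) %% 4^(m - 1L)) + 1L, , drop = FALSE]
      denom <- rowSums(cm) + 4 * pseudocount + backoffAlpha
      tab <- (cm + pseudocount + backoffAlpha * pr) / pmax(denom, 1e-300)
      tab[denom == 0, ] <- 0.25     # unobserved contexts at pseudocount 0
      prevTab <- tab
    }
    positionTables[[p]] <- list(prevTab)
  }
  new("WeightedArrayMatrix", order = order, windowLength = W,
      positionTables = positionTables, pseudocount = pseudocount,
      nFloorLog = nFloorLog)
}

#' Score one window under a weighted array matrix
#'
#' @param wam a [WeightedArrayMatrix-class].
#' @param window DNA string or integer codes of length `windowLength`.
#' @return log-probability of the window.
#' @export
scoreWAM <- function(wam, window) {
  codes <- if (is.character(window)) encodeDNA(window) else as.integer(window)
  if (length(codes) != wam@windowLength)
    stop("window length ", length(codes), " does not match windowLength ",
         wam@windowLength)
  total <- 0
  for (p in seq_len(wam@windowLength)) {
    m <- min(wam@order, p - 1L)
    if (codes[p] == 0L || (m > 0L && any(codes[(p - m):(p - 1L)] == 0L))) {
      total <- total + wam@nFloorLog
      next
    }
    ctx <- 1L
    if (m > 0L)
      for (t in seq_len(m)) ctx <- ctx + (codes[p - t] - 1L) * 4^(t - 1)
    total <- total + log(wam@positionTables[[p]][[1L]][ctx, codes[p]])
  }
  total
}

## Vector of window scores over a whole sequence: out[s] is the score of the
## window starting at s (-1e30 where the window would overrun the sequence).
.wamPositionScores <- function(wam, codes) {
  L <- length(codes)
  W <- wam@windowLength
  out <- rep(.NEG_INF, L)
  if (L < W) return(out)
  acc <- numeric(L - W + 1L)
  for (p in seq_len(W)) {
    m <- min(wam@order, p - 1L)
    idx <- contextIndex(codes, m)
    lp <- rep(wam@nFloorLog, L)
    ok <- which(idx > 0L & codes > 0L)
    if (length(ok)) {
      tab <- wam@positionTables[[p]][[1L]]
      lp[ok] <- log(tab[cbind(idx[ok], codes[ok])])
    }
    ## a window starting at s has its p-th position at s + p - 1; positions
    ## with fewer than m preceding bases inside the window never occur because
    ## m <= p - 1.  Positions with context reaching before the sequence start
    ## (idx == 0 from sequence edge) are floored, matching scoreWAM only when
    ## there is genuine N content; guard by recomputing edge starts directly.
    acc <- acc + lp[p:(L - W + p)]
  }
  out[seq_len(L - W + 1L)] <- acc
  ## contexts are window-internal, so only the first (order) sequence
  ## positions can disagree with scoreWAM; fix them exactly.
  for (s in seq_len(min(wam@order, L - W + 1L)))
    out[s] <- scoreWAM(wam, codes[s:(s + W - 1L)])
  out
}

#' Literal motif emission
#'
#' @param motifs character vector of words (equal length), e.g. the stop
#'   codons.
#' @param probs probabilities (recycled uniform when NULL); normalised.
#' @return a [MotifEmission-class].
#' @export
motifEmission <- function(motifs, probs = NULL) {
  if (is.null(probs)) probs <- rep(1, length(motifs))
  probs <- probs / sum(probs)
  new("MotifEmission", motifs = toupper(motifs), logp = log(probs))
}

#' @keywords internal
scoreMotif <- function(em, window) {
  w <- if (is.character(window)) toupper(window) else decodeDNA(window)
  i <- match(w, em@motifs)
  if (is.na(i)) .NEG_INF else em@logp[i]
}

## Window-score vector for a motif emission.
.motifPositionScores <- function(em, codes) {
  L <- length(codes)
  W <- nchar(em@motifs[1])
  out <- rep(.NEG_INF, L)
  if (L < W) return(out)
  mot <- lapply(em@motifs, encodeDNA)
  for (mi in seq_along(mot)) {
    hit <- rep(TRUE, L - W + 1L)
    for (p in seq_len(W)) hit <- hit & codes[p:(L - W + p)] == mot[[mi]][p]
    out[seq_len(L - W + 1L)][hit] <- pmax(out[seq_len(L - W + 1L)][hit], em@logp[mi])
  }
  out
}
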