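## k-order (optionally three-periodic) Markov chain emission models.

#' Train a Markov chain emission model
#'
#' Counts (context, next base) events over the training sequences and converts
#' them to conditional probabilities with an additive pseudocount:
#' (count + c) / (total + 4c).  For a three-periodic chain the counts land in
#' the table of the codon position of each site.  Backoff tables of orders
#' 0..k-1 are trained from the same data so that the first k positions of a
#' decoded segment can be scored on segment-local context.  Positions whose
#' base or context window contains an ambiguity character are excluded.
#'
#' @param seqs list of DNA character strings (or integer code vectors).
#' @param order context length k (>= 0).
#' @param periodic logical; TRUE for a three-periodic chain.
#' @param pseudocount additive pseudocount per table cell.
#' @param phases integer vector (recycled) of codon-phase offsets: the codon
#'   position of the first base of each sequence (0, 1 or 2).
#' @param nFloorLog log-probability floor for ambiguity contexts.
#' @return a [MarkovChainModel-class] object.
#' @export
trainMarkov <- function(seqs, order, periodic = FALSE, pseudocount = 0.01,
                        phases = 0L, nFloorLog = log(0.25)) {
  if (!length(seqs)) stop("at least one training sequence is required")
  if (is.character(seqs)) seqs <- as.list(seqs)
  codes <- lapply(seqs, function(s) if (is.character(s)) encodeDNA(s) else as.integer(s))
  phases <- rep_len(as.integer(phases), length(codes))
  nph <- if (periodic) 3L else 1L
  order <- as.integer(order)

  counts <- lapply(seq_len(nph), function(ph)
    lapply(0:order, function(m) matrix(0, nrow = 4^m, ncol = 4L)))

  for (si in seq_along(codes)) {
    x <- codes[[si]]
    L <- length(x)
    if (L == 0L) next
    phv <- if (periodic) ((seq_len(L) - 1L + phases[si]) %% 3L) + 1L else rep(1L, L)
    for (m in 0:order) {
      idx <- contextIndex(x, m)
      ok <- which(idx > 0L & x > 0L)
      if (!length(ok)) next
      for (ph in seq_len(nph)) {
        sel <- ok[phv[ok] == ph]
        if (!length(sel)) next
        flat <- (idx[sel] - 1L) * 4L + x[sel]
        tab <- tabulate(flat, nbins = 4^m * 4L)
        counts[[ph]][[m + 1L]] <- counts[[ph]][[m + 1L]] +
          matrix(tab, nrow = 4^m, ncol = 4L, byrow = TRUE)
      }
    }
  }

  tables <- lapply(counts, function(byorder) lapply(byorder, function(cm) {
    cm <- cm + pseudocount
    rs <- rowSums(cm)
    cm[rs == 0, ] <- 0.25        # unobserved contexts at pseudocount 0
    cm / pmax(rowSums(cm), 1e-300)
  }))
  new("MarkovChainModel", order = order, periodic = periodic, tables = tables,
      pseudocount = pseudocount, nFloorLog = nFloorLog)
}

## Per-position log-probabilities under a single phase table, using contexts of
## exactly `r` preceding bases (effective order capped by position).  Floor is
## applied at ambiguity bases/contexts and at positions with fewer than r
## preceding bases when exact = TRUE callers never consult them.
.mkvLogp <- function(model, codes, r, phaseTable) {
  L <- length(codes)
  out <- rep(model@nFloorLog, L)
  if (L == 0L) return(out)
  idx <- contextIndex(codes, r)
  ok <- which(idx > 0L & codes > 0L)
  if (length(ok)) {
    tab <- model@tables[[phaseTable]][[r + 1L]]
    out[ok] <- log(tab[cbind(idx[ok], codes[ok])])
  }
  out
}

#' Score a sequence under a Markov chain model
#'
#' The first k positions are scored with shortened (backoff) contexts of
#' orders 0..k-1, so the score depends only on the scored segment itself.
#'
#' @param model a [MarkovChainModel-class].
#' @param x DNA string or integer codes.
#' @param startPhase codon phase of the first position (periodic models).
#' @return total log-probability (0 for an empty sequence).
#' @export
scoreMarkov <- function(model, x, startPhase = 0L) {
  codes <- if (is.character(x)) encodeDNA(x) else as.integer(x)
  L <- length(codes)
  if (L == 0L) return(0)
  k <- model@order
  total <- 0
  for (i in seq_len(min(k, L))) {
    ph <- if (model@periodic) ((i - 1L + startPhase) %% 3L) + 1L else 1L
    total <- total + .mkvLogp(model, codes, i - 1L, ph)[i]
  }
  if (L > k) {
    if (model@periodic) {
      for (t in 1:3) {
        pos <- (k + 1L):L
        sel <- pos[((pos - 1L + startPhase) %% 3L) + 1L == t]
        if (length(sel)) total <- total + sum(.mkvLogp(model, codes, k, t)[sel])
      }
    } else {
      total <- total + sum(.mkvLogp(model, codes, k, 1L)[(k + 1L):L])
    }
  }
  total
}

## Emission arrays for the explicit-duration decoder.
##
## For a state with this model and entry phase e0, a segment [s, e] scores
##   cum[c][e] - cum[c][s-1] + sum_{r=0}^{min(k, e-s+1)-1} bc[s, r+1]
## where c = (s-1) %% 3.  `penalty` (length L) is added per covered position
## (used for constraint masks and in-frame stop exclusion); it flows through
## cum only, so the backoff correction leaves it intact.
.markovEmissionArrays <- function(model, codes, entryPhase = 0L, penalty = NULL) {
  L <- length(codes)
  k <- model@order
  nph <- if (model@periodic) 3L else 1L
  Gt <- lapply(seq_len(nph), function(t) .mkvLogp(model, codes, k, t))
  ## penalty: per-position addend, either a vector (applies whatever the
  ## segment start residue class) or an L x 3 matrix with one column per start
  ## class (s-1) mod 3, which lets callers forbid positions only in a given
  ## reading frame (in-frame stop exclusion).
  if (is.null(penalty)) penalty <- numeric(L)
  pm <- if (is.matrix(penalty)) penalty else matrix(penalty, nrow = L, ncol = 3L)
  ## forbidden positions (penalty at or below the -inf sentinel) must not
  ## enter the cumulative sums: at that magnitude floating-point addition
  ## erases the real scores.  They are tracked as a prefix count instead and
  ## any segment covering one is rejected outright by the decoder.
  forbidden <- pm < .NEG_GUARD
  pm[forbidden] <- 0
  fcum <- rbind(0L, apply(forbidden, 2L, function(col) cumsum(as.integer(col))))
  storage.mode(fcum) <- "integer"

  cum <- matrix(0, nrow = L + 1L, ncol = 3L)
  j <- seq_len(L)
  classConst <- !is.matrix(penalty) && !model@periodic
  for (c in 0:2) {
    t <- if (model@periodic) (((j - 1L) - c + entryPhase) %% 3L) + 1L else rep(1L, L)
    g <- numeric(L)
    for (tt in seq_len(nph)) {
      sel <- t == tt
      g[sel] <- Gt[[tt]][sel]
    }
    cum[, c + 1L] <- c(0, cumsum(g + pm[, c + 1L]))
    if (classConst) { cum[, 2:3] <- cum[, 1L]; break }
  }

  bc <- matrix(0, nrow = L, ncol = max(k, 0L))
  if (k > 0L) {
    for (r in 0:(k - 1L)) {
      t <- if (model@periodic) ((r + entryPhase) %% 3L) + 1L else 1L
      Br <- .mkvLogp(model, codes, r, t)
      Gfull <- Gt[[t]]
      v <- rep(0, L)
      valid <- seq_len(L - r)               # segment start s with s+r <= L
      v[valid] <- Br[valid + r] - Gfull[valid + r]
      bc[, r + 1L] <- v
    }
  }
  list(type = 0L, cum = cum, bc = bc, k = k, fcum = fcum,
       periodic = model@periodic)
}
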