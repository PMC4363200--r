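## State duration models: smoothed empirical length distributions with a
## geometric tail, or fixed lengths.

#' Fixed-length duration model
#' @param length the single admissible segment length.
#' @return a [DurationModel-class] of kind "fixed".
#' @export
fixedDuration <- function(length) {
  new("DurationModel", kind = "fixed", fixedLength = as.integer(length),
      support = c(as.integer(length), as.integer(length)), step = 1L,
      logp = 0, tailLogMass = -Inf, tailRate = 0.5, tailCap = NA_integer_)
}

#' Smoothed empirical duration model
#'
#' Histogram of observed lengths over a regular grid, convolved with a
#' triangular kernel of the given half-width, mixed with a small uniform floor
#' (so every grid length in the support has positive probability) and
#' renormalised.  Lengths above the support maximum are absorbed into a
#' geometric tail whose rate is fitted to their mean excess.
#'
#' @param lengths observed segment lengths (positive integers).
#' @param bandwidth triangular-kernel half-width in grid steps; NA uses
#'   max(2, support width / 50).
#' @param support integer c(min, max); defaults to the observed range.
#' @param step grid step (3 for codon-quantised coding durations).
#' @param floor uniform floor mixed over the support.
#' @return a [DurationModel-class] of kind "empirical".
#' @export
smoothDurations <- function(lengths, bandwidth = NA, support = NULL, step = 1L,
                            floor = 1e-6, tailCap = NA) {
  if (!length(lengths)) stop("lengths must be non-empty")
  lengths <- as.integer(round(lengths))
  step <- as.integer(step)
  if (is.null(support)) support <- range(lengths)
  smin <- as.integer(support[1]); smax <- as.integer(support[2])
  smax <- smin + ((smax - smin) %/% step) * step
  grid <- seq(smin, smax, by = step)
  ng <- length(grid)
  if (is.na(bandwidth)) bandwidth <- max(2L, as.integer((smax - smin) / step / 50))
  bandwidth <- as.integer(bandwidth)

  over <- lengths[lengths > smax]
  inside <- pmax(lengths[lengths <= smax], smin)
  gi <- pmin(pmax(round((inside - smin) / step) + 1L, 1L), ng)
  hist <- tabulate(gi, nbins = ng)

  if (bandwidth > 0L && ng > 1L) {
    kw <- (bandwidth + 1L) - abs(seq(-bandwidth, bandwidth))
    kw <- kw / sum(kw)
    sm <- numeric(ng)
    for (d in seq(-bandwidth, bandwidth)) {
      w <- kw[d + bandwidth + 1L]
      src <- seq_len(ng)
      dst <- src + d
      keep <- dst >= 1L & dst <= ng
      sm[dst[keep]] <- sm[dst[keep]] + w * hist[src[keep]]
      ## reflect mass that would fall off the support back onto the edge
      off <- !keep
      if (any(off)) {
        edge <- ifelse(dst[off] < 1L, 1L, ng)
        sm[edge] <- sm[edge] + w * hist[src[off]]
      }
    }
    hist <- sm
  }

  tailMass <- max(length(over) / length(lengths), 1e-4)
  if (length(over)) {
    meanExcessSteps <- mean((over - smax) / step)
    tailRate <- min(max(1 / meanExcessSteps, 1e-6), 1 - 1e-6)
  } else tailRate <- 0.5

  p <- hist / sum(hist)
  p <- (1 - floor) * p + floor / ng
  p <- p * (1 - tailMass)
  new("DurationModel", kind = "empirical", fixedLength = NA_integer_,
      support = c(smin, smax), step = step, logp = log(p),
      tailLogMass = log(tailMass), tailRate = tailRate,
      tailCap = as.integer(tailCap))
}

#' Log-probability of a duration
#' @param dm a [DurationModel-class].
#' @param d segment length.
#' @return log-probability; a large negative sentinel for inadmissible d.
#' @export
durationLogProb <- function(dm, d) {
  if (dm@kind == "fixed") return(ifelse(d == dm@fixedLength, 0, .NEG_INF))
  out <- rep(.NEG_INF, length(d))
  onGrid <- (d - dm@support[1]) %% dm@step == 0
  inSupp <- onGrid & d >= dm@support[1] & d <= dm@support[2]
  out[inSupp] <- dm@logp[(d[inSupp] - dm@support[1]) %/% dm@step + 1L]
  inTail <- onGrid & d > dm@support[2]
  if (any(inTail)) {
    i <- (d[inTail] - dm@support[2]) %/% dm@step
    out[inTail] <- dm@tailLogMass + log(dm@tailRate) +
      (i - 1) * log(1 - dm@tailRate)
  }
  out
}

## Materialise a duration model on its grid up to dcap, for the decoder.
## The geometric tail is materialised up to a bounded extension beyond the
## support so decoding cost stays linear in the support width.
.materializeDurations <- function(dm, dcap) {
  if (dm@kind == "fixed") {
    if (dm@fixedLength > dcap)
      return(list(dmin = 1L, dstep = 1L, durlog = .NEG_INF))
    return(list(dmin = dm@fixedLength, dstep = 1L, durlog = 0))
  }
  width <- dm@support[2] - dm@support[1]
  ext <- if (is.na(dm@tailCap)) dm@support[2] + max(width, 300L %/% dm@step * dm@step)
         else if (dm@tailCap < 0L) as.integer(dcap)
         else dm@support[2] + dm@tailCap * dm@step
  dmax <- min(as.integer(dcap), as.integer(ext))
  dmax <- dm@support[1] + ((dmax - dm@support[1]) %/% dm@step) * dm@step
  if (dmax < dm@support[1])
    return(list(dmin = 1L, dstep = 1L, durlog = .NEG_INF))
  d <- seq(dm@support[1], dmax, by = dm@step)
  list(dmin = dm@support[1], dstep = dm@step, durlog = durationLogProb(dm, d))
}
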