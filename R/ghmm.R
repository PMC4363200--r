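## Generalised-HMM decoding: the explicit-duration Viterbi wrapper and the
## exhaustive parse-enumeration oracle used to validate it.

#' Construct a GHMM specification
#'
#' @param states character vector of state names.
#' @param transitions named square probability matrix (rows = from,
#'   cols = to); row sums plus `end` must be 1.
#' @param begin named initial-state probabilities (sum 1).
#' @param end named per-state end probabilities.
#' @param emissions named list of emission models.
#' @param durations named list of [DurationModel-class] objects.
#' @param entryPhase named integer vector of codon entry phases for periodic
#'   states (defaults to 0).
#' @return a validated [GhmmSpec-class].
#' @export
ghmmSpec <- function(states, transitions, begin, end, emissions, durations,
                     entryPhase = NULL) {
  n <- length(states)
  tr <- matrix(0, n, n, dimnames = list(states, states))
  if (is.null(rownames(transitions))) tr[, ] <- transitions
  else tr[rownames(transitions), colnames(transitions)] <- transitions
  bg <- setNames(numeric(n), states)
  if (is.null(names(begin))) bg[] <- begin else bg[names(begin)] <- begin
  en <- setNames(numeric(n), states)
  if (is.null(names(end))) en[] <- end else en[names(end)] <- end
  ep <- setNames(integer(n), states)
  if (!is.null(entryPhase)) ep[names(entryPhase)] <- as.integer(entryPhase)
  new("GhmmSpec", states = states, transitions = tr, begin = bg, end = en,
      emissions = emissions[states], durations = durations[states],
      entryPhase = ep)
}

.safeLog <- function(p) ifelse(p > 0, log(p), .NEG_INF)

## Build the per-state decoder inputs for one sequence.
## penalties: optional named list state -> numeric(L); for Markov states the
## vector is added per covered position, for window states (WAM / motif) it is
## added to the score of a window *starting* at each position.
.decoderInputs <- function(spec, codes, penalties = NULL, dcap = NULL) {
  L <- length(codes)
  if (is.null(dcap)) dcap <- L
  lapply(seq_along(spec@states), function(qi) {
    st <- spec@states[qi]
    em <- spec@emissions[[st]]
    pen <- if (!is.null(penalties) && !is.null(penalties[[st]])) penalties[[st]] else NULL
    dm <- .materializeDurations(spec@durations[[st]], dcap)
    if (is(em, "MarkovChainModel")) {
      arr <- .markovEmissionArrays(em, codes, entryPhase = spec@entryPhase[[st]],
                                   penalty = pen)
      c(list(dmin = dm$dmin, dstep = dm$dstep, durlog = dm$durlog), arr)
    } else {
      w <- if (is(em, "WeightedArrayMatrix")) .wamPositionScores(em, codes)
           else .motifPositionScores(em, codes)
      if (!is.null(pen)) w <- w + pen
      w[w < .NEG_GUARD] <- .NEG_INF
      list(dmin = dm$dmin, dstep = dm$dstep, durlog = dm$durlog,
           type = 1L, wscore = w)
    }
  })
}

#' Explicit-duration Viterbi decoding
#'
#' Finds the maximum-log-probability segmentation of a sequence under a
#' [GhmmSpec-class], optionally subject to per-position constraints supplied
#' as additive penalty tracks (a forbidden state/boundary carries a -1e30
#' penalty).  Ties are broken deterministically: the path whose segment-end
#' sequence is lexicographically smallest wins, then state order decides.
#'
#' @param spec a [GhmmSpec-class].
#' @param x DNA string or integer codes.
#' @param penalties optional named list (state -> numeric of length L):
#'   per-covered-position addends for Markov states, per-window-start addends
#'   for fixed-window states.
#' @param dcap optional cap on segment durations (default: sequence length).
#' @return list with elements `ok` (FALSE means no admissible parse),
#'   `logprob`, and `path` (data.frame state/start/end).
#' @export
viterbiDecode <- function(spec, x, penalties = NULL, dcap = NULL) {
  codes <- if (is.character(x)) encodeDNA(x) else as.integer(x)
  L <- length(codes)
  if (L == 0L)
    return(list(ok = TRUE, logprob = 0,
                path = data.frame(state = character(), start = integer(),
                                  end = integer())))
  inputs <- .decoderInputs(spec, codes, penalties, dcap)
  res <- .viterbi_cpp(L, .safeLog(spec@transitions), .safeLog(spec@begin),
                      .safeLog(spec@end), inputs)
  if (!isTRUE(res$ok)) return(list(ok = FALSE, logprob = -Inf, path = NULL))
  p <- res$path
  list(ok = TRUE, logprob = res$logprob,
       path = data.frame(state = spec@states[p[, 1]], start = p[, 2],
                         end = p[, 3], stringsAsFactors = FALSE))
}

## Naive segment score: independent of the cumulative-array machinery; used by
## the enumeration oracle and in tests.
.segmentScore <- function(spec, state, codes, s, e, penalties = NULL) {
  em <- spec@emissions[[state]]
  pen <- if (!is.null(penalties) && !is.null(penalties[[state]])) penalties[[state]] else NULL
  if (is(em, "MarkovChainModel")) {
    sc <- scoreMarkov(em, codes[s:e], startPhase = spec@entryPhase[[state]])
    if (!is.null(pen)) {
      sc <- sc + if (is.matrix(pen)) sum(pen[s:e, (s - 1L) %% 3L + 1L])
                 else sum(pen[s:e])
    }
    return(sc)
  }
  W <- if (is(em, "WeightedArrayMatrix")) em@windowLength else nchar(em@motifs[1])
  if (e - s + 1L != W) return(.NEG_INF)
  sc <- if (is(em, "WeightedArrayMatrix")) scoreWAM(em, codes[s:e])
        else scoreMotif(em, codes[s:e])
  if (!is.null(pen)) sc <- sc + pen[s]
  sc
}

.pathLess <- function(endsA, statesA, endsB, statesB) {
  m <- min(length(endsA), length(endsB))
  for (i in seq_len(m)) if (endsA[i] != endsB[i]) return(endsA[i] < endsB[i])
  if (length(endsA) != length(endsB)) return(length(endsA) < length(endsB))
  for (i in seq_len(m)) if (statesA[i] != statesB[i]) return(statesA[i] < statesB[i])
  FALSE
}

#' Exhaustive parse enumeration (testing oracle)
#'
#' Enumerates every admissible segmentation of a short sequence and returns
#' the argmax under the same tie-break as [viterbiDecode()].  Refuses
#' sequences longer than 30 nt or models with more than 6 states.
#'
#' @inheritParams viterbiDecode
#' @return same structure as [viterbiDecode()].
#' @export
enumerateParses <- function(spec, x, penalties = NULL) {
  codes <- if (is.character(x)) encodeDNA(x) else as.integer(x)
  L <- length(codes)
  if (L > 30L) stop("enumeration oracle refuses sequences longer than 30 nt")
  if (length(spec@states) > 6L) stop("enumeration oracle refuses more than 6 states")
  if (L == 0L)
    return(list(ok = TRUE, logprob = 0,
                path = data.frame(state = character(), start = integer(),
                                  end = integer())))
  n <- length(spec@states)
  ltrans <- .safeLog(spec@transitions)
  lbegin <- .safeLog(spec@begin)
  lend <- .safeLog(spec@end)

  ## precompute admissible (state, start, end) segment scores
  segsc <- array(.NEG_INF, dim = c(n, L, L))
  durv <- vector("list", n)
  for (q in seq_len(n)) {
    dm <- spec@durations[[spec@states[q]]]
    md <- .materializeDurations(dm, L)
    ds <- seq(md$dmin, by = md$dstep, length.out = length(md$durlog))
    keep <- md$durlog > .NEG_GUARD & ds <= L
    durv[[q]] <- list(d = ds[keep], lp = md$durlog[keep])
    for (s in seq_len(L)) for (di in seq_along(durv[[q]]$d)) {
      e <- s + durv[[q]]$d[di] - 1L
      if (e > L) next
      segsc[q, s, e] <- .segmentScore(spec, spec@states[q], codes, s, e, penalties)
    }
  }

  best <- new.env()
  best$score <- -Inf; best$ends <- NULL; best$states <- NULL

  rec <- function(pos, lastQ, score, ends, states) {
    if (score < best$score - 1e-6) return(invisible(NULL))
    if (pos > L) {
      fin <- score + (if (is.null(lastQ)) .NEG_INF else lend[lastQ])
      if (fin < .NEG_GUARD) return(invisible(NULL))
      if (!is.finite(best$score)) {
        best$score <- fin; best$ends <- ends; best$states <- states
        return(invisible(NULL))
      }
      tol <- 1e-10 * (1 + abs(best$score))
      if (fin > best$score + tol) {
        best$score <- fin; best$ends <- ends; best$states <- states
      } else if (fin >= best$score - tol &&
                 .pathLess(ends, states, best$ends, best$states)) {
        best$score <- fin; best$ends <- ends; best$states <- states
      }
      return(invisible(NULL))
    }
    for (q in seq_len(n)) {
      tp <- if (is.null(lastQ)) lbegin[q] else ltrans[lastQ, q]
      if (tp < .NEG_GUARD) next
      dv <- durv[[q]]
      for (di in seq_along(dv$d)) {
        e <- pos + dv$d[di] - 1L
        if (e > L) next
        emsc <- segsc[q, pos, e]
        if (emsc < .NEG_GUARD) next
        rec(e + 1L, q, score + tp + dv$lp[di] + emsc,
            c(ends, e), c(states, q))
      }
    }
    invisible(NULL)
  }
  rec(1L, NULL, 0, integer(), integer())

  if (!is.finite(best$score) || best$score < .NEG_GUARD)
    return(list(ok = FALSE, logprob = -Inf, path = NULL))
  starts <- c(1L, head(best$ends, -1L) + 1L)
  list(ok = TRUE, logprob = unname(best$score),
       path = data.frame(state = spec@states[best$states], start = starts,
                         end = best$ends, stringsAsFactors = FALSE))
}

#' Serialize a GHMM specification to flat text
#'
#' Writes the state list, transition table and emission/duration summaries in
#' a diffable plain-text format.
#'
#' @param spec a [GhmmSpec-class].
#' @param path output file.
#' @export
writeGhmmSpec <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("states:", paste(spec@states, collapse = " ")), con)
  writeLines("transitions:", con)
  for (i in seq_along(spec@states)) for (j in seq_along(spec@states))
    if (spec@transitions[i, j] > 0)
      writeLines(sprintf("  %s -> %s %.8g", spec@states[i], spec@states[j],
                         spec@transitions[i, j]), con)
  writeLines("begin:", con)
  for (i in seq_along(spec@states)) if (spec@begin[i] > 0)
    writeLines(sprintf("  %s %.8g", spec@states[i], spec@begin[i]), con)
  writeLines("end:", con)
  for (i in seq_along(spec@states)) if (spec@end[i] > 0)
    writeLines(sprintf("  %s %.8g", spec@states[i], spec@end[i]), con)
  for (st in spec@states) {
    em <- spec@emissions[[st]]
    dm <- spec@durations[[st]]
    dtxt <- if (dm@kind == "fixed") paste0("fixed ", dm@fixedLength)
            else sprintf("empirical [%d,%d] step %d", dm@support[1],
                         dm@support[2], dm@step)
    writeLines(sprintf("state %s: emission %s, duration %s", st, class(em)[1], dtxt), con)
    if (is(em, "MarkovChainModel")) {
      for (ph in seq_along(em@tables)) {
        tab <- em@tables[[ph]][[em@order + 1L]]
        writeLines(sprintf("  phase %d order %d:", ph - 1L, em@order), con)
        for (r in seq_len(nrow(tab)))
          writeLines(paste0("    ", paste(sprintf("%.6g", tab[r, ]), collapse = " ")), con)
      }
    }
  }
  invisible(path)
}
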