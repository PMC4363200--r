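## Stage 2: genome-space GHMM with an explicit intron sub-model, trained from
## the stage-1 genes and decoded over selected genomic regions under
## transcript-derived splice-boundary constraints.
##
## Phase bookkeeping: the Kozak window ends at the ATG, so coding exons start
## at codon position 0 after it.  Donor windows cover the last 2 exonic
## nucleotides plus the intron start (GT..); acceptor windows cover the intron
## end (..AG) plus the first 2 exonic nucleotides.  Exon states are expanded
## by (entry phase p, exit phase q): durations satisfy d = (q - p) mod 3, a
## donor after an exon with exit phase q carries tag q through the intron
## chain, and the acceptor resumes an exon with entry phase (q + 1) mod 3
## (the 2 + 2 exonic nucleotides inside donor and acceptor advance the frame).

.s2States <- function() {
  ex <- as.vector(outer(0:2, 0:2, function(p, q) sprintf("exon_%d_%d", p, q)))
  intr <- as.vector(vapply(0:2, function(q)
    sprintf(c("donor_%d", "ispacer1_%d", "branch_%d", "ispacer2_%d", "acceptor_%d"),
            q), character(5)))
  c("intergenic", "kozak_start", sort(ex), intr, "stop_codon")
}

#' Collect evidenced introns from transcript alignments
#'
#' Introns are the gaps between consecutive exon blocks of one transcript.
#' For unknown-strand transcripts the orientation is inferred from the GT..AG
#' rule where possible.  Non-canonical introns keep their length (it feeds the
#' maximum-intron rule) but are excluded from splice-signal training.
#'
#' @param genome DNAStringSet.
#' @param txa [TranscriptAlignments-class].
#' @return data.frame(contig, start, end, strand, len, canonical) with an
#'   attribute `codes`: list of oriented intron code vectors including 2
#'   exonic nucleotides on each side.
#' @export
evidencedIntrons <- function(genome, txa) {
  rows <- list(); seqs <- list(); n <- 0L
  for (i in seq_len(nrow(txa@tx))) {
    id <- txa@tx$transcript_id[i]
    ex <- txa@exons[txa@exons$transcript_id == id, , drop = FALSE]
    if (nrow(ex) < 2L) next
    contig <- ex$contig[1]
    cseq <- as.character(genome[[contig]])
    clen <- nchar(cseq)
    for (j in seq_len(nrow(ex) - 1L)) {
      is <- ex$end[j] + 1L; ie <- ex$start[j + 1L] - 1L
      if (ie < is) next
      lo <- max(is - 2L, 1L); hi <- min(ie + 2L, clen)
      flanked <- encodeDNA(substr(cseq, lo, hi))
      str <- txa@tx$strand[i]
      din5 <- substr(cseq, is, is + 1L); din3 <- substr(cseq, ie - 1L, ie)
      if (str == "*")
        str <- if (din5 == "GT" && din3 == "AG") "+"
               else if (din5 == "CT" && din3 == "AC") "-"
               else "+"
      oriented <- if (str == "-") revcompCodes(flanked) else flanked
      canonical <- if (str == "+") din5 == "GT" && din3 == "AG"
                   else din5 == "CT" && din3 == "AC"
      canonical <- canonical && lo == is - 2L && hi == ie + 2L
      n <- n + 1L
      rows[[n]] <- data.frame(contig = contig, start = is, end = ie,
                              strand = str, len = ie - is + 1L,
                              canonical = canonical, stringsAsFactors = FALSE)
      seqs[[n]] <- oriented
    }
  }
  out <- if (n) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), len = integer(), canonical = logical())
  out <- unique(cbind(out, idx = seq_len(nrow(out))))
  dupkey <- paste(out$contig, out$start, out$end, out$strand)
  keep <- !duplicated(dupkey)
  attrcodes <- seqs[out$idx[keep]]
  out <- out[keep, setdiff(names(out), "idx"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "codes") <- attrcodes
  out
}

#' Maximum intron length rule
#'
#' 10\% longer than the longest evidenced intron, capped at 5000 nt; the cap
#' is removable (`disable_intron_cap`).  With no evidenced introns the
#' configured default applies.
#'
#' @param intronLengths evidenced intron lengths.
#' @param cfg a [sporeCallConfig()].
#' @return integer maximum intron length.
#' @export
maxIntronLength <- function(intronLengths, cfg = sporeCallConfig()) {
  if (!length(intronLengths)) return(as.integer(cfg$default_max_intron))
  m <- as.integer(ceiling(cfg$intron_factor * max(intronLengths)))
  if (!isTRUE(cfg$disable_intron_cap)) m <- min(m, as.integer(cfg$intron_cap))
  m
}

#' Fit donor/acceptor boundary lengths by positional composition
#'
#' Moving outward from the invariant GT (resp. inward from the AG), each
#' intronic position's base composition is compared against the pooled
#' composition of the intron interior with a chi-square test (df = 3, p =
#' `chi_p`); the boundary extends to the furthest significant position.  The
#' returned lengths are totals including the 2 exonic nucleotides, each in
#' [4, `boundary_max`].  With fewer than `min_introns_for_fit` evidenced
#' introns the configured default applies.
#'
#' @param intronCodes list of oriented intronic code vectors (no exon flanks).
#' @param cfg a [sporeCallConfig()].
#' @return c(donor = total donor length, acceptor = total acceptor length).
#' @export
fitBoundaryLengths <- function(intronCodes, cfg = sporeCallConfig()) {
  fallback <- c(donor = min(cfg$default_boundary_intronic + cfg$exon_ext,
                            cfg$boundary_max),
                acceptor = min(cfg$default_boundary_intronic + cfg$exon_ext,
                               cfg$boundary_max))
  if (length(intronCodes) < cfg$min_introns_for_fit) return(fallback)

  ## interior reference composition: exclude the candidate boundary region at
  ## the donor side and everything within the branch-point search window of
  ## the acceptor, so that genuine 3'-context signal (branch motif,
  ## pyrimidine tract) does not contaminate the null.  Short introns that
  ## have no such clean interior contribute nothing.
  interior <- integer(4)
  trim <- cfg$boundary_interior_trim
  endTrim <- max(cfg$branch_window[2], cfg$boundary_interior_trim)
  for (x in intronCodes) {
    len <- length(x)
    if (len < trim + endTrim + 5L) next
    rng <- (trim + 1L):(len - endTrim)
    v <- x[rng]; v <- v[v > 0L]
    interior <- interior + tabulate(v, nbins = 4L)
  }
  if (sum(interior) < 100L) {
    ## fall back to the middle third when the introns are uniformly short
    for (x in intronCodes) {
      len <- length(x)
      rng <- (len %/% 3L + 1L):(2L * len %/% 3L)
      v <- x[rng]; v <- v[v > 0L]
      interior <- interior + tabulate(v, nbins = 4L)
    }
  }
  pInt <- (interior + 1) / sum(interior + 1)
  crit <- qchisq(1 - cfg$chi_p, df = 3)
  maxIntronic <- cfg$boundary_max - cfg$exon_ext

  ## extend the boundary position by position while the composition remains
  ## significantly different from the interior; stop at the first position
  ## that does not differ.  (Taking the furthest significant position over the
  ## whole candidate range instead would inflate the boundary through multiple
  ## testing: at p = 0.01 over ~18 candidate positions, a spurious extension
  ## would occur in roughly one fit in six.)
  testPos <- function(fromEnd) {
    furthest <- 2L
    for (pos in 3:maxIntronic) {
      counts <- integer(4)
      for (x in intronCodes) {
        if (length(x) < pos + 6L) next
        b <- if (fromEnd) x[length(x) - pos + 1L] else x[pos]
        if (b > 0L) counts[b] <- counts[b] + 1L
      }
      nTot <- sum(counts)
      if (nTot < 20L) break
      expd <- pInt * nTot
      x2 <- sum((counts - expd)^2 / expd)
      if (x2 > crit) furthest <- pos else break
    }
    furthest
  }
  c(donor = testPos(FALSE) + cfg$exon_ext,
    acceptor = testPos(TRUE) + cfg$exon_ext)
}

## Train the branch-point WAM: initialised from the fungal branch consensus
## (TACTAAC) as a soft prior, then two rounds of argmax alignment within the
## allowed window upstream of the acceptor.  Also returns the donor->branch
## and branch->acceptor spacer lengths implied by the final alignment.
.trainBranch <- function(intronCodes, donorIntronic, acceptorIntronic, cfg) {
  W <- cfg$branch_width
  wam <- trainWAM(list("TACTAAC"), order = 1L, pseudocount = 0.5,
                  nFloorLog = cfg$n_floor_log)
  picks <- NULL
  for (round in 1:2) {
    wins <- list(); s1 <- integer(); s2 <- integer()
    for (x in intronCodes) {
      len <- length(x)
      loEnd <- max(donorIntronic + W + 1L, len - cfg$branch_window[2])
      hiEnd <- len - max(acceptorIntronic + 1L, cfg$branch_window[1])
      if (hiEnd - W + 1L < loEnd - W + 1L || hiEnd < loEnd) next
      starts <- (loEnd - W + 1L):(hiEnd - W + 1L)
      starts <- starts[starts >= donorIntronic + 2L]
      if (!length(starts)) next
      sc <- vapply(starts, function(s) scoreWAM(wam, x[s:(s + W - 1L)]), 0)
      s <- starts[which.max(sc)]
      wins <- c(wins, list(x[s:(s + W - 1L)]))
      s1 <- c(s1, s - donorIntronic - 1L)
      s2 <- c(s2, (len - acceptorIntronic) - (s + W - 1L))
    }
    if (length(wins) < 5L) break
    wam <- trainWAM(wins, order = 1L, pseudocount = cfg$pseudocount,
                    nFloorLog = cfg$n_floor_log, backoffAlpha = cfg$wam_backoff)
    picks <- list(s1 = s1, s2 = s2, windows = wins)
  }
  list(wam = wam, spacer1 = if (is.null(picks)) integer() else picks$s1,
       spacer2 = if (is.null(picks)) integer() else picks$s2)
}

## Per-gene structural statistics of a stage-1 gene set, used for stage-2
## transition and duration estimation.
.geneStructureStats <- function(genes) {
  exonAdj <- integer(); exitCounts <- integer(3)
  nFinalExit0 <- 0L; nNonFinalExit0 <- 0L
  for (id in genes@genes$gene_id) {
    seg <- genes@segments[genes@segments$gene_id == id, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    strand <- genes@genes$strand[genes@genes$gene_id == id]
    if (strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    lens <- seg$end - seg$start + 1L
    m <- length(lens)
    cum <- cumsum(lens)
    for (i in seq_len(m)) {
      adj <- lens[i] - (if (i == 1L) 3L else 2L) - (if (i == m) 3L else 2L)
      if (adj >= 1L) exonAdj <- c(exonAdj, adj)
      q <- if (i == m) 0L else (cum[i] - 2L) %% 3L
      exitCounts[q + 1L] <- exitCounts[q + 1L] + 1L
      if (q == 0L) {
        if (i == m) nFinalExit0 <- nFinalExit0 + 1L
        else nNonFinalExit0 <- nNonFinalExit0 + 1L
      }
    }
  }
  list(exonAdj = exonAdj, exitCounts = exitCounts,
       pStop = (nFinalExit0 + 1) / (nFinalExit0 + nNonFinalExit0 + 2))
}

## Subset an empirical duration model to durations congruent to r mod 3.
.residueDuration <- function(dm, r) {
  grid <- seq(dm@support[1], dm@support[2], by = dm@step)
  sel <- which(grid %% 3L == r)
  if (!length(sel)) {
    lo <- dm@support[1] + ((r - dm@support[1]) %% 3L)
    return(new("DurationModel", kind = "empirical", fixedLength = NA_integer_,
               support = c(lo, lo), step = 3L, logp = log(1e-6),
               tailLogMass = log(1e-4), tailRate = dm@tailRate,
               tailCap = dm@tailCap))
  }
  new("DurationModel", kind = "empirical", fixedLength = NA_integer_,
      support = c(grid[sel[1]], grid[sel[length(sel)]]), step = 3L,
      logp = dm@logp[sel], tailLogMass = dm@tailLogMass - log(3),
      tailRate = dm@tailRate, tailCap = dm@tailCap)
}

#' Train the stage-2 genome-space GHMM
#'
#' Coding, Kozak and stop models are reused from the stage-1 model (default);
#' the intergenic chain is trained from sequence outside the stage-1 genes;
#' donor, branch-point and acceptor weighted array matrices and the intron
#' spacer chains are trained from the canonical evidenced introns, with
#' boundary lengths fitted by [fitBoundaryLengths()].
#'
#' @param stage1Genes kept stage-1 [GeneSet-class] (training uses all of them).
#' @param stage1Model the trained [Stage1Model-class].
#' @param genome DNAStringSet.
#' @param txa [TranscriptAlignments-class].
#' @param cfg a [sporeCallConfig()].
#' @return a [Stage2Model-class].
#' @export
trainStage2 <- function(stage1Genes, stage1Model, genome, txa,
                        cfg = sporeCallConfig()) {
  s1 <- stage1Model@spec
  pc <- cfg$pseudocount; nf <- cfg$n_floor_log
  bw <- if (is.na(cfg$duration_bandwidth)) NA else cfg$duration_bandwidth

  introns <- evidencedIntrons(genome, txa)
  icodes <- attr(introns, "codes")
  canonical <- which(introns$canonical & introns$len >= cfg$min_intron)
  canCodes <- lapply(icodes[canonical], function(x) x[3:(length(x) - 2L)])

  if (!length(canonical))
    warning("no canonical evidenced introns; intron model uses defaults",
            call. = FALSE)
  bl <- fitBoundaryLengths(canCodes, cfg)
  dL <- as.integer(bl["donor"]); aL <- as.integer(bl["acceptor"])
  dI <- dL - cfg$exon_ext; aI <- aL - cfg$exon_ext
  maxIntron <- maxIntronLength(introns$len, cfg)

  ## splice-signal WAMs (windows include the 2 exonic nt)
  flanked <- icodes[canonical]
  donorWins <- Filter(Negate(is.null), lapply(flanked, function(x)
    if (length(x) >= dL + aL) x[1:dL] else NULL))
  accWins <- Filter(Negate(is.null), lapply(flanked, function(x)
    if (length(x) >= dL + aL) x[(length(x) - aL + 1L):length(x)] else NULL))
  mkFallbackWam <- function(consensus) trainWAM(list(consensus), order = 1L,
                                                pseudocount = 0.5, nFloorLog = nf)
  donorWam <- if (length(donorWins) >= 5L)
    trainWAM(donorWins, order = 1L, pseudocount = pc, nFloorLog = nf,
             backoffAlpha = cfg$wam_backoff)
  else mkFallbackWam(paste0(strrep("A", cfg$exon_ext), "GT",
                            strrep("A", dI - 2L)))
  accWam <- if (length(accWins) >= 5L)
    trainWAM(accWins, order = 1L, pseudocount = pc, nFloorLog = nf,
             backoffAlpha = cfg$wam_backoff)
  else mkFallbackWam(paste0(strrep("T", aI - 2L), "AG",
                            strrep("A", cfg$exon_ext)))

  br <- .trainBranch(canCodes, dI, aI, cfg)

  ## spacer chains
  sp1Seqs <- list(); sp2Seqs <- list()
  for (x in canCodes) {
    len <- length(x)
    mid <- x[(dI + 1L):(len - aI)]
    if (length(mid) >= 10L) {
      half <- length(mid) %/% 2L
      sp1Seqs <- c(sp1Seqs, list(mid[1:half]))
      sp2Seqs <- c(sp2Seqs, list(mid[(half + 1L):length(mid)]))
    }
  }
  mkChain <- function(seqs, order, what) {
    if (!length(seqs)) seqs <- list(encodeDNA("ACGTACGT"))
    k <- .effectiveOrder(sum(lengths(seqs)), order, cfg$order_reduce_quota,
                         what = what)
    trainMarkov(seqs, order = k, pseudocount = pc, nFloorLog = nf)
  }
  sp1Em <- mkChain(sp1Seqs, cfg$spacer_order, "intron spacer")
  sp2Em <- sp1Em

  ## intergenic chain and durations from the stage-1 gene geometry
  gaps <- integer(); interSeqs <- list(); total <- 0L
  for (contig in unique(stage1Genes@genes$contig)) {
    ids <- stage1Genes@genes$gene_id[stage1Genes@genes$contig == contig]
    seg <- stage1Genes@segments[stage1Genes@segments$gene_id %in% ids, , drop = FALSE]
    spans <- if (nrow(seg)) mergeIntervals(
      vapply(ids, function(id) min(seg$start[seg$gene_id == id]), 0L),
      vapply(ids, function(id) max(seg$end[seg$gene_id == id]), 0L))
      else data.frame(start = integer(), end = integer())
    clen <- Biostrings::width(genome[contig])
    cseq <- as.character(genome[[contig]])
    prev <- 1L
    bounds <- rbind(spans, data.frame(start = clen + 1L, end = clen + 1L))
    for (i in seq_len(nrow(bounds))) {
      if (bounds$start[i] > prev) {
        gap <- c(prev, bounds$start[i] - 1L)
        gaps <- c(gaps, gap[2] - gap[1] + 1L)
        if (total < cfg$intergenic_train_cap) {
          interSeqs <- c(interSeqs, list(encodeDNA(substr(cseq, gap[1], gap[2]))))
          total <- total + gap[2] - gap[1] + 1L
        }
      }
      prev <- max(prev, bounds$end[i] + 1L)
    }
  }
  interEm <- mkChain(interSeqs, cfg$intergenic_order, "intergenic")

  stats <- .geneStructureStats(stage1Genes)
  exonDur <- smoothDurations(if (length(stats$exonAdj)) stats$exonAdj else c(100L, 300L),
                             bandwidth = bw,
                             support = c(1L, max(stats$exonAdj, 30L)),
                             floor = cfg$duration_floor)
  gaps <- pmin(gaps[gaps >= 1L], cfg$intergenic_dur_cap)
  if (!length(gaps)) gaps <- c(200L, 500L)
  interDur <- smoothDurations(gaps, bandwidth = bw,
                              support = c(1L, max(gaps)),
                              floor = cfg$duration_floor, tailCap = 60L)

  ## spacer durations bounded so that every intron length stays within
  ## [min_intron, maxIntron]
  s2lo <- max(cfg$branch_window[1] - aI + 1L, 1L)
  s2hi <- max(cfg$branch_window[2] - aI - cfg$branch_width + 1L, s2lo)
  s2obs <- br$spacer2[br$spacer2 >= s2lo & br$spacer2 <= s2hi]
  sp2Dur <- smoothDurations(if (length(s2obs)) s2obs else seq(s2lo, s2hi),
                            bandwidth = bw, support = c(s2lo, s2hi),
                            floor = cfg$duration_floor, tailCap = 0L)
  s1hi <- maxIntron - dI - aI - cfg$branch_width - s2lo
  s1lo <- max(1L, cfg$min_intron - dI - aI - cfg$branch_width - s2lo)
  s1obs <- br$spacer1[br$spacer1 >= s1lo & br$spacer1 <= s1hi]
  sp1Dur <- smoothDurations(if (length(s1obs)) s1obs else seq(s1lo, min(s1lo + 100L, s1hi)),
                            bandwidth = bw, support = c(s1lo, s1hi),
                            floor = cfg$duration_floor, tailCap = 0L)

  ## ---- assemble the model specification ----------------------------------
  states <- .s2States()
  ems <- list(); durs <- list(); ep <- integer()
  ems[["intergenic"]] <- interEm; durs[["intergenic"]] <- interDur
  ems[["kozak_start"]] <- s1@emissions[["kozak_start"]]
  durs[["kozak_start"]] <- fixedDuration(cfg$kozak_width)
  ems[["stop_codon"]] <- s1@emissions[["stop_codon"]]
  durs[["stop_codon"]] <- fixedDuration(3L)
  cdsEm <- s1@emissions[["cds"]]
  for (p in 0:2) for (q in 0:2) {
    st <- sprintf("exon_%d_%d", p, q)
    ems[[st]] <- cdsEm
    durs[[st]] <- .residueDuration(exonDur, (q - p) %% 3L)
    ep[st] <- p
  }
  for (q in 0:2) {
    ems[[sprintf("donor_%d", q)]] <- donorWam
    durs[[sprintf("donor_%d", q)]] <- fixedDuration(dL)
    ems[[sprintf("ispacer1_%d", q)]] <- sp1Em
    durs[[sprintf("ispacer1_%d", q)]] <- sp1Dur
    ems[[sprintf("branch_%d", q)]] <- br$wam
    durs[[sprintf("branch_%d", q)]] <- fixedDuration(cfg$branch_width)
    ems[[sprintf("ispacer2_%d", q)]] <- sp2Em
    durs[[sprintf("ispacer2_%d", q)]] <- sp2Dur
    ems[[sprintf("acceptor_%d", q)]] <- accWam
    durs[[sprintf("acceptor_%d", q)]] <- fixedDuration(aL)
  }

  n <- length(states)
  tr <- matrix(0, n, n, dimnames = list(states, states))
  phaseDist <- (stats$exitCounts + 1) / (sum(stats$exitCounts) + 3)
  endMass <- 0.02
  tr["intergenic", "intergenic"] <- cfg$intergenic_self_p
  tr["intergenic", "kozak_start"] <- 1 - cfg$intergenic_self_p - endMass
  for (q in 0:2) tr["kozak_start", sprintf("exon_0_%d", q)] <- phaseDist[q + 1L]
  pStop <- stats$pStop
  for (p in 0:2) {
    tr[sprintf("exon_%d_0", p), "stop_codon"] <- pStop
    tr[sprintf("exon_%d_0", p), "donor_0"] <- 1 - pStop
    tr[sprintf("exon_%d_1", p), "donor_1"] <- 1
    tr[sprintf("exon_%d_2", p), "donor_2"] <- 1
  }
  for (q in 0:2) {
    tr[sprintf("donor_%d", q), sprintf("ispacer1_%d", q)] <- 1
    tr[sprintf("ispacer1_%d", q), sprintf("branch_%d", q)] <- 1
    tr[sprintf("branch_%d", q), sprintf("ispacer2_%d", q)] <- 1
    tr[sprintf("ispacer2_%d", q), sprintf("acceptor_%d", q)] <- 1
    pNew <- (q + 1L) %% 3L
    for (q2 in 0:2)
      tr[sprintf("acceptor_%d", q), sprintf("exon_%d_%d", pNew, q2)] <- phaseDist[q2 + 1L]
  }
  tr["stop_codon", "intergenic"] <- 1
  begin <- setNames(numeric(n), states); begin["intergenic"] <- 1
  end <- setNames(numeric(n), states); end["intergenic"] <- endMass

  spec <- ghmmSpec(states, tr, begin, end, emissions = ems, durations = durs,
                   entryPhase = ep)
  new("Stage2Model", spec = spec, donorLength = dL, acceptorLength = aL,
      maxIntron = as.integer(maxIntron), minIntron = as.integer(cfg$min_intron),
      config = unclass(cfg))
}

#' Build the splice-boundary constraint track
#'
#' Intron boundaries (donor and acceptor sites) are disallowed wherever an
#' aligned transcript covers the position on the same strand, except within
#' `relax_nt` (50) of that transcript's ends.  Unstranded or unknown-strand
#' transcripts forbid boundaries on both strands.
#'
#' @param txa [TranscriptAlignments-class].
#' @param genome DNAStringSet.
#' @param cfg a [sporeCallConfig()].
#' @return named list per contig: list(fwd, rev) logical vectors, TRUE where a
#'   boundary is forbidden.
#' @export
buildConstraints <- function(txa, genome, cfg = sporeCallConfig()) {
  out <- lapply(names(genome), function(contig) {
    L <- Biostrings::width(genome[contig])
    list(fwd = logical(L), rev = logical(L))
  })
  names(out) <- names(genome)
  for (i in seq_len(nrow(txa@tx))) {
    id <- txa@tx$transcript_id[i]
    ex <- txa@exons[txa@exons$transcript_id == id, , drop = FALSE]
    contig <- ex$contig[1]
    span <- c(min(ex$start), max(ex$end))
    relLo <- span[1] + cfg$relax_nt - 1L
    relHi <- span[2] - cfg$relax_nt + 1L
    strands <- if (txa@tx$strand[i] == "+") "fwd"
               else if (txa@tx$strand[i] == "-") "rev"
               else c("fwd", "rev")
    for (j in seq_len(nrow(ex))) {
      lo <- max(ex$start[j], relLo + 1L)
      hi <- min(ex$end[j], relHi - 1L)
      if (hi < lo) next
      for (s in strands) out[[contig]][[s]][lo:hi] <- TRUE
    }
  }
  out
}

## Frame read-through test: can removing this evidenced intron extend an ORF
## across it without hitting a stop?  Reads the genomic sequence through the
## intron in each frame entering it; TRUE if some frame crosses stop-free.
.readsThroughIntron <- function(cseq, istart, iend, strand, margin = 30L) {
  lo <- max(istart - margin, 1L); hi <- min(iend + margin, nchar(cseq))
  codes <- encodeDNA(substr(cseq, lo, hi))
  if (strand == "-") {
    codes <- revcompCodes(codes)
    tmp <- length(codes) - (iend - lo + 1L) + 1L   # intron start in oriented coords
    iLen <- iend - istart + 1L
    is2 <- tmp; ie2 <- tmp + iLen - 1L
  } else {
    is2 <- istart - lo + 1L; ie2 <- iend - lo + 1L
  }
  st <- stopCodonStarts(codes)
  for (fr in 0:2) {
    starts <- seq(fr + 1L, length(codes) - 2L, by = 3L)
    inReach <- starts[starts >= is2 - 2L - margin & starts <= ie2]
    if (!length(inReach)) next
    if (!any(st[inReach])) return(TRUE)
  }
  FALSE
}

#' Select regions for genome-space prediction
#'
#' Discards error-prone stage-1 genes (single-exon genes; genes whose ORF can
#' be extended 5' beyond the supporting transcript, i.e. suspected
#' incomplete), flags alternative-splicing windows where an evidenced intron
#' can be read through stop-free, and returns the genomic windows to decode:
#' everything outside the retained genes, padded by `flank_pad` and split to
#' at most `max_window` with overlap.
#'
#' @param prediction output of [predictStage1()] (genes + parses).
#' @param txa [TranscriptAlignments-class].
#' @param genome DNAStringSet.
#' @param cfg a [sporeCallConfig()].
#' @return list(kept, discarded [GeneSet-class]es, reasons, windows
#'   data.frame(contig, start, end, alt)).
#' @export
selectRegions <- function(prediction, txa, genome, cfg = sporeCallConfig()) {
  genes <- prediction$genes
  g <- genes@genes; s <- genes@segments
  reasons <- setNames(rep(NA_character_, nrow(g)), g$gene_id)

  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    seg <- s[s$gene_id == id, , drop = FALSE]
    if (nrow(seg) == 1L) { reasons[id] <- "single_exon"; next }
    ## suspected incomplete: in transcript space, walk upstream codons from
    ## the ATG; an open frame all the way to the transcript 5' end means the
    ## ORF can extend beyond the supporting transcript
    p <- prediction$parses[[g$transcript_id[i]]]
    if (is.null(p)) next
    path <- p$path
    koz <- which(path$state == "kozak_start")
    gidx <- which(vapply(koz, function(kk) {
      tstart <- path$end[kk] - 2L
      lifted <- liftToGenome(p$spliced, tstart, path$end[kk])
      lifted$start[1] == min(seg$start) || lifted$end[nrow(lifted)] == max(seg$end)
    }, TRUE))
    if (!length(gidx)) next
    tstart <- path$end[koz[gidx[1]]] - 2L
    codes <- p$spliced@codes
    open <- TRUE
    j <- tstart - 3L
    while (j >= 1L) {
      if (isStopCodon(codes, j)) { open <- FALSE; break }
      j <- j - 3L
    }
    if (open && tstart > 3L) reasons[id] <- "suspected_incomplete"
  }

  kept <- is.na(reasons[g$gene_id])
  keptSet <- newGeneSet(g[kept, , drop = FALSE],
                        s[s$gene_id %in% g$gene_id[kept], , drop = FALSE])
  discSet <- newGeneSet(g[!kept, , drop = FALSE],
                        s[s$gene_id %in% g$gene_id[!kept], , drop = FALSE])

  ## alternative-splice loci: evidenced introns that read through stop-free
  introns <- evidencedIntrons(genome, txa)
  altLoci <- list()
  for (i in seq_len(nrow(introns))) {
    cseq <- as.character(genome[[introns$contig[i]]])
    if (.readsThroughIntron(cseq, introns$start[i], introns$end[i],
                            introns$strand[i]))
      altLoci <- c(altLoci, list(introns[i, c("contig", "start", "end")]))
  }
  altDf <- if (length(altLoci)) do.call(rbind, altLoci)
           else data.frame(contig = character(), start = integer(), end = integer())

  ## genomic windows: complement of kept gene spans, padded and split
  wins <- list(); nw <- 0L
  for (contig in names(genome)) {
    clen <- Biostrings::width(genome[contig])
    ids <- keptSet@genes$gene_id[keptSet@genes$contig == contig]
    spans <- if (length(ids)) mergeIntervals(
      vapply(ids, function(id) min(keptSet@segments$start[keptSet@segments$gene_id == id]), 0L),
      vapply(ids, function(id) max(keptSet@segments$end[keptSet@segments$gene_id == id]), 0L))
      else data.frame(start = integer(), end = integer())
    prev <- 1L
    bounds <- rbind(spans, data.frame(start = clen + 1L, end = clen + 1L))
    for (i in seq_len(nrow(bounds))) {
      if (bounds$start[i] > prev) {
        lo <- max(prev - cfg$flank_pad, 1L)
        hi <- min(bounds$start[i] - 1L + cfg$flank_pad, clen)
        nw <- nw + 1L
        wins[[nw]] <- data.frame(contig = contig, start = lo, end = hi)
      }
      prev <- max(prev, bounds$end[i] + 1L)
    }
  }
  windows <- if (nw) do.call(rbind, wins)
             else data.frame(contig = character(), start = integer(), end = integer())
  ## split oversized windows with overlap
  if (nrow(windows)) {
    splitW <- list(); nsw <- 0L
    for (i in seq_len(nrow(windows))) {
      lo <- windows$start[i]; hi <- windows$end[i]
      while (hi - lo + 1L > cfg$max_window) {
        nsw <- nsw + 1L
        splitW[[nsw]] <- data.frame(contig = windows$contig[i], start = lo,
                                    end = lo + cfg$max_window - 1L)
        lo <- lo + cfg$max_window - cfg$window_overlap
      }
      nsw <- nsw + 1L
      splitW[[nsw]] <- data.frame(contig = windows$contig[i], start = lo, end = hi)
    }
    windows <- do.call(rbind, splitW)
    windows$alt <- vapply(seq_len(nrow(windows)), function(i)
      any(altDf$contig == windows$contig[i] &
          altDf$start <= windows$end[i] & altDf$end >= windows$start[i]), TRUE)
  } else windows$alt <- logical(0)
  rownames(windows) <- NULL

  list(kept = keptSet, discarded = discSet,
       reasons = reasons[!is.na(reasons)], windows = windows,
       alt_introns = altDf)
}

## Build window-start penalty vectors for the donor/acceptor states of one
## decoded window: GT/AG dinucleotide admissibility plus the constraint track.
.splicePenalties <- function(codes, dL, aL, forb, winStart, winEnd, reverse) {
  L <- length(codes)
  toGenomic <- function(i) if (reverse) winEnd - i + 1L else winStart + i - 1L
  dPen <- rep(0, L); aPen <- rep(0, L)
  ## donor window at s: intron starts at s + 2 (GT)
  sd <- seq_len(max(L - dL + 1L, 0L))
  gOK <- codes[sd + 2L] == 3L & codes[sd + 3L] == 4L
  dPen[sd][!gOK] <- .NEG_INF
  if (!is.null(forb)) {
    gpos <- toGenomic(sd + 2L)
    dPen[sd][forb[gpos]] <- .NEG_INF
  }
  if (L >= dL) dPen[(L - dL + 2L):L] <- .NEG_INF else dPen[] <- .NEG_INF
  ## acceptor window at s: intron ends at s + aL - 3 (..AG)
  sa <- seq_len(max(L - aL + 1L, 0L))
  aOK <- codes[sa + aL - 4L] == 1L & codes[sa + aL - 3L] == 3L
  aPen[sa][!aOK] <- .NEG_INF
  if (!is.null(forb)) {
    gpos <- toGenomic(sa + aL - 3L)
    aPen[sa][forb[gpos]] <- .NEG_INF
  }
  if (L >= aL) aPen[(L - aL + 2L):L] <- .NEG_INF else aPen[] <- .NEG_INF
  list(donor = dPen, acceptor = aPen)
}

## Extract gene models from one stage-2 window parse (window coordinates).
.genesFromS2Parse <- function(model, codes, path, pen) {
  idx <- which(path$state == "kozak_start")
  if (!length(idx)) return(list())
  genes <- list()
  for (gi in seq_along(idx)) {
    i <- idx[gi]
    segs <- list(); score <- 0
    j <- i
    repeat {
      st <- path$state[j]; s <- path$start[j]; e <- path$end[j]
      score <- score + .segmentScore(model@spec, st, codes, s, e, pen) +
        durationLogProb(model@spec@durations[[st]], e - s + 1L)
      if (st == "kozak_start") segs <- c(segs, list(c(e - 2L, e)))
      else if (grepl("^exon_", st)) segs <- c(segs, list(c(s, e)))
      else if (grepl("^donor_", st)) segs <- c(segs, list(c(s, s + 1L)))
      else if (grepl("^acceptor_", st)) segs <- c(segs, list(c(e - 1L, e)))
      else if (st == "stop_codon") { segs <- c(segs, list(c(s, e))); break }
      j <- j + 1L
      if (j > nrow(path)) return(genes)   # truncated parse: drop this run
    }
    m <- do.call(rbind, segs)
    m <- mergeIntervals(m[, 1], m[, 2])
    ## length-stable log-odds: subtract the intergenic emission over the span
    score <- score - .segmentScore(model@spec, "intergenic", codes,
                                   path$start[i], path$end[j], NULL)
    genes[[length(genes) + 1L]] <- list(cds = m, score = score)
  }
  genes
}

#' Predict genes from genome sequence (stage 2)
#'
#' Viterbi decoding of each selected window on both strands (independent
#' decodings; where coding regions of opposite-strand candidates overlap, the
#' higher-scoring gene wins).  Intron placement obeys the GT..AG rule and the
#' transcript-derived constraint track.
#'
#' @param model a [Stage2Model-class].
#' @param selection output of [selectRegions()].
#' @param constraints output of [buildConstraints()].
#' @param genome DNAStringSet.
#' @param cfg a [sporeCallConfig()].
#' @return a [GeneSet-class] with provenance "stage2".
#' @export
predictStage2 <- function(model, selection, constraints, genome,
                          cfg = sporeCallConfig()) {
  windows <- selection$windows
  dL <- model@donorLength; aL <- model@acceptorLength
  allGenes <- list(); ng <- 0L

  stopPen <- function(codes) {
    pms <- lapply(0:2, function(p) {
      L <- length(codes)
      pm <- matrix(0, nrow = L, ncol = 3L)
      stops <- which(stopCodonStarts(codes))
      if (length(stops)) pm[cbind(stops, (stops + p - 1L) %% 3L + 1L)] <- .NEG_INF
      pm
    })
    names(pms) <- paste0("p", 0:2)
    pms
  }

  for (wi in seq_len(nrow(windows))) {
    contig <- windows$contig[wi]
    a <- windows$start[wi]; b <- windows$end[wi]
    cseq <- substr(as.character(genome[[contig]]), a, b)
    fwdCodes <- encodeDNA(cseq)
    cand <- list()
    for (rev in c(FALSE, TRUE)) {
      codes <- if (rev) revcompCodes(fwdCodes) else fwdCodes
      forb <- constraints[[contig]][[if (rev) "rev" else "fwd"]]
      sp <- .splicePenalties(codes, dL, aL, forb, a, b, rev)
      pms <- stopPen(codes)
      pen <- list()
      for (p in 0:2) for (q in 0:2)
        pen[[sprintf("exon_%d_%d", p, q)]] <- pms[[p + 1L]]
      for (q in 0:2) {
        pen[[sprintf("donor_%d", q)]] <- sp$donor
        pen[[sprintf("acceptor_%d", q)]] <- sp$acceptor
      }
      pen[["kozak_start"]] <- .kozakAtgPenalty(codes, cfg$kozak_width)
      dec <- viterbiDecode(model@spec, codes, penalties = pen)
      if (!isTRUE(dec$ok)) next
      gl <- .genesFromS2Parse(model, codes, dec$path, pen)
      for (g in gl) {
        cds <- g$cds
        if (rev) {
          gs <- b - cds$end + 1L; ge <- b - cds$start + 1L
          cds <- data.frame(start = rev(gs), end = rev(ge))
        } else {
          cds <- data.frame(start = cds$start + a - 1L, end = cds$end + a - 1L)
        }
        cand[[length(cand) + 1L]] <- list(cds = cds, score = g$score,
                                          strand = if (rev) "-" else "+")
      }
    }
    if (!length(cand)) next
    ## opposite-strand overlap reconciliation within the window: keep the
    ## higher-scoring gene where coding spans overlap
    if (length(cand) > 1L) {
      spans <- t(vapply(cand, function(g) c(min(g$cds$start), max(g$cds$end)), c(0, 0)))
      sc <- vapply(cand, `[[`, 0, "score")
      ord <- order(-sc)
      keep <- logical(length(cand)); taken <- NULL
      for (i in ord) {
        clash <- !is.null(taken) && any(taken[, 1] <= spans[i, 2] & spans[i, 1] <= taken[, 2])
        if (!clash) { keep[i] <- TRUE; taken <- rbind(taken, spans[i, , drop = FALSE]) }
      }
      cand <- cand[keep]
    }
    for (g in cand) {
      ng <- ng + 1L
      allGenes[[ng]] <- list(contig = contig, strand = g$strand, cds = g$cds,
                             score = g$score, alt = windows$alt[wi])
    }
  }
  if (!ng) return(emptyGeneSet())

  ## deduplicate across overlapping windows; validate reading frames
  keys <- vapply(allGenes, function(g)
    paste(g$contig, g$strand, paste(g$cds$start, g$cds$end, collapse = ","),
          sep = "|"), "")
  allGenes <- allGenes[!duplicated(keys)]
  genes <- list(); segs <- list(); n <- 0L
  for (g in allGenes) {
    cseq <- as.character(genome[[g$contig]])
    sseq <- paste(substring(cseq, g$cds$start, g$cds$end), collapse = "")
    if (g$strand == "-") sseq <- revcompDNA(sseq)
    len <- nchar(sseq)
    if (len %% 3L != 0L || len < 6L) next
    if (substr(sseq, 1, 3) != "ATG") next
    if (!substr(sseq, len - 2L, len) %in% .STOP_CODONS) next
    codons <- substring(sseq, seq(1L, len - 5L, by = 3L), seq(3L, len - 3L, by = 3L))
    if (any(codons %in% .STOP_CODONS)) next   # splice-straddling stop: reject
    n <- n + 1L
    gid <- sprintf("s2.%s.%d", g$contig, n)
    genes[[n]] <- data.frame(gene_id = gid, transcript_id = NA_character_,
                             contig = g$contig, strand = g$strand,
                             provenance = "stage2", complete5 = TRUE,
                             complete3 = TRUE, score = g$score, alt = g$alt,
                             stringsAsFactors = FALSE)
    segs[[n]] <- data.frame(gene_id = gid, start = g$cds$start, end = g$cds$end,
                            phase = .segmentPhases(g$cds$start, g$cds$end,
                                                   g$strand))
  }
  if (!n) return(emptyGeneSet())
  newGeneSet(do.call(rbind, genes), do.call(rbind, segs))
}
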