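## Seeded synthetic fungal genomes with known truth: compact gene spacing,
## short GT..AG introns with planted donor/branch/acceptor signals, Kozak
## context, codon-biased coding sequence, and the transcript-assembly
## pathologies the predictor targets (merged transcripts, 5' truncation,
## false-positive introns, unexpressed genes, unstranded data).

#' Parameters for the synthetic genome generator
#'
#' @param ... named overrides of the defaults listed in the source.  The
#'   defaults describe a compact, intron-poor fungal genome: lognormal
#'   intergenic gaps around 400 nt, 1-6 exons per gene, 40-200 nt introns,
#'   codon bias drawn once per run from a Dirichlet over an order-2
#'   three-periodic chain (stop-codon completions zeroed), and consensus
#'   splice/Kozak signals of realistic strength.
#' @return named list of class `SynthParams`.
#' @export
synthParams <- function(...) {
  p <- list(
    seed = 1L,
    n_genes = 100L,
    contig = "chr1",
    contig_len = NA_integer_,          # NA: grows to fit
    gap_meanlog = log(400), gap_sdlog = 0.5, gap_range = c(150L, 3000L),
    exon_probs = c(0.40, 0.25, 0.15, 0.10, 0.06, 0.04),
    cds_shape = 4, cds_scale = 100,    # gamma, x3 -> mean ~1200 nt
    cds_range = c(300L, 4500L),
    intron_meanlog = log(80), intron_sdlog = 0.35, intron_range = c(40L, 200L),
    utr5_meanlog = log(80), utr5_sdlog = 0.4, utr5_range = c(20L, 250L),
    utr3_meanlog = log(120), utr3_sdlog = 0.4, utr3_range = c(30L, 300L),
    coding_concentration = 1,
    coding_base_weights = c(0.20, 0.30, 0.30, 0.20),     # GC-rich coding (A,C,G,T)
    background_concentration = 8,
    background_base_weights = c(0.30, 0.20, 0.20, 0.30), # AT-rich intergenic/UTR
    kozak_consensus = "AAACAAAA",      # the 8 nt preceding ATG
    kozak_strength = 0.7,
    donor_consensus = "AAGT",          # intron positions 3..6 (after GT)
    donor_strength = 0.85,
    acceptor_consensus = "TTTC",       # intron positions -6..-3 (before AG)
    acceptor_strength = 0.8,
    branch_consensus = "TACTAAC",
    branch_strength = 0.9,
    branch_dist = c(10L, 40L),         # branch end to intron end
    stop_probs = c(TAA = 0.5, TGA = 0.3, TAG = 0.2),
    frac_unexpressed = 0,
    frac_truncated5 = 0,
    frac_merged_ss = 0,                # fraction of genes in same-strand merges
    frac_merged_sas = 0,               # fraction of genes in sense-antisense merges
    frac_fp_intron = 0,
    stranded = TRUE
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown synthesis parameters: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  fr <- c(p$frac_unexpressed, p$frac_truncated5, p$frac_merged_ss,
          p$frac_merged_sas, p$frac_fp_intron)
  if (any(fr < 0 | fr > 1)) stop("corruption fractions must lie in [0, 1]")
  if (sum(fr) > 1) stop("corruption fractions jointly infeasible (sum > 1)")
  class(p) <- c("SynthParams", "list")
  p
}

## Dirichlet-drawn conditional tables for an order-2 chain.  For the periodic
## (coding) chain the codon-position-2 table has stop-codon completions zeroed
## so the chain never emits an in-frame stop: the generating conditionals are
## then exactly recoverable from emitted sequence.  `baseWeights` skews the
## expected base usage: coding sequence is generated GC-richer than the AT-rich
## intergenic background, mirroring real fungal genomes (this is also what
## makes the reverse complement of coding sequence resemble coding sequence
## more than UTRs do, the driver of antisense false positives in
## transcript-space prediction).
.dirichletTables <- function(concentration, periodic,
                             baseWeights = c(1, 1, 1, 1)) {
  nph <- if (periodic) 3L else 1L
  w <- 4 * baseWeights / sum(baseWeights)
  tabs <- lapply(seq_len(nph), function(ph) {
    m <- matrix(rgamma(16 * 4, shape = concentration *
                                 rep(w, each = 16)), nrow = 16)
    m <- m + 1e-4
    m / rowSums(m)
  })
  if (periodic) {
    ## phase-3 context = codon positions 0,1 (idx = 1 + (b2-1) + (b1-1)*4)
    ta <- 1L + (1L - 1L) + (4L - 1L) * 4L   # "TA"
    tg <- 1L + (3L - 1L) + (4L - 1L) * 4L   # "TG"
    tabs[[3]][ta, c(1L, 3L)] <- 0           # TAA, TAG
    tabs[[3]][tg, 1L] <- 0                  # TGA
    tabs[[3]] <- tabs[[3]] / rowSums(tabs[[3]])
  }
  tabs
}

## Sample n bases from an order-2 chain (list of per-phase 16x4 tables).
.sampleChain <- function(tabs, n, phase0 = 0L, init = NULL) {
  if (n <= 0L) return(integer())
  periodic <- length(tabs) == 3L
  out <- integer(n)
  prev2 <- if (is.null(init)) sample.int(4L, 2L, replace = TRUE) else init
  for (i in seq_len(n)) {
    ph <- if (periodic) ((i - 1L + phase0) %% 3L) + 1L else 1L
    idx <- 1L + (prev2[2L] - 1L) + (prev2[1L] - 1L) * 4L
    b <- sample.int(4L, 1L, prob = tabs[[ph]][idx, ])
    out[i] <- b
    prev2 <- c(prev2[2L], b)
  }
  out
}

.consensusDraw <- function(consensus, strength) {
  cs <- encodeDNA(consensus)
  keep <- runif(length(cs)) < strength
  cs[!keep] <- sample.int(4L, sum(!keep), replace = TRUE)
  cs
}

## One intron of length li (>= 24): GT + donor consensus + spacer + branch
## 7-mer ending 10-40 nt before the intron end + spacer + acceptor consensus
## + AG.
.makeIntron <- function(li, p, bg) {
  seq <- .sampleChain(bg, li)
  seq[1:2] <- c(3L, 4L)                      # GT
  dcons <- .consensusDraw(p$donor_consensus, p$donor_strength)
  seq[3:(2L + length(dcons))] <- dcons
  db <- sample(p$branch_dist[1]:p$branch_dist[2], 1L)
  db <- min(db, li - 2L - length(dcons) - nchar(p$branch_consensus))
  bstart <- li - db - nchar(p$branch_consensus) + 1L
  seq[bstart:(li - db)] <- .consensusDraw(p$branch_consensus, p$branch_strength)
  acons <- .consensusDraw(p$acceptor_consensus, p$acceptor_strength)
  seq[(li - 1L - length(acons)):(li - 2L)] <- acons
  seq[(li - 1L):li] <- c(1L, 3L)             # AG
  seq
}

.clipInt <- function(x, range) as.integer(pmin(pmax(round(x), range[1]), range[2]))

#' Generate a synthetic genome with known annotation and transcript assembly
#'
#' Deterministic under the seed in `params`.  Returns the genome, the true
#' gene models, the (possibly corrupted) transcript alignments, per-transcript
#' corruption labels and the generating model tables for recovery tests.
#'
#' @param params a [synthParams()] list.
#' @return a [SyntheticTruth-class].
#' @export
generateSynthetic <- function(params = synthParams()) {
  p <- params
  set.seed(p$seed)
  coding <- .dirichletTables(p$coding_concentration, periodic = TRUE,
                             baseWeights = p$coding_base_weights)
  bg <- .dirichletTables(p$background_concentration, periodic = FALSE,
                         baseWeights = p$background_base_weights)
  stopsEnc <- list(TAA = c(4L, 1L, 1L), TGA = c(4L, 3L, 1L), TAG = c(4L, 1L, 3L))

  n <- p$n_genes
  pieces <- list(); np <- 0L
  pos <- 0L
  genes <- list(); segs <- list(); exonsL <- list()
  geneInfo <- list()

  addPiece <- function(codes) {
    np <<- np + 1L
    pieces[[np]] <<- codes
    pos <<- pos + length(codes)
  }

  for (gi in seq_len(n)) {
    gap <- .clipInt(rlnorm(1, p$gap_meanlog, p$gap_sdlog), p$gap_range)
    addPiece(.sampleChain(bg, gap))

    strand <- sample(c("+", "-"), 1L)
    nex <- sample(seq_along(p$exon_probs), 1L, prob = p$exon_probs)
    cdsLen <- .clipInt(3 * rgamma(1, p$cds_shape, scale = p$cds_scale), p$cds_range)
    cdsLen <- (cdsLen %/% 3L) * 3L
    u5 <- .clipInt(rlnorm(1, p$utr5_meanlog, p$utr5_sdlog), p$utr5_range)
    u3 <- .clipInt(rlnorm(1, p$utr3_meanlog, p$utr3_sdlog), p$utr3_range)

    ## sense-orientation coding sequence
    body <- .sampleChain(coding, cdsLen - 6L, phase0 = 0L, init = c(4L, 3L))
    stopC <- stopsEnc[[sample(names(p$stop_probs), 1L, prob = p$stop_probs)]]
    cds <- c(1L, 4L, 3L, body, stopC)

    ## intron breakpoints: CDS nucleotide counts before each intron
    nintr <- nex - 1L
    maxIntr <- max((cdsLen - 60L) %/% 30L, 0L)
    nintr <- min(nintr, maxIntr)
    brk <- integer(0)
    if (nintr > 0L) {
      cand <- seq(30L, cdsLen - 30L)
      brk <- sort(sample(cand, nintr))
      while (length(brk) > 1L && any(diff(brk) < 30L))
        brk <- sort(sample(cand, nintr))
    }
    ilens <- if (nintr > 0L)
      .clipInt(rlnorm(nintr, p$intron_meanlog, p$intron_sdlog), p$intron_range)
    else integer(0)

    utr5 <- .sampleChain(bg, u5)
    kz <- .consensusDraw(p$kozak_consensus, p$kozak_strength)
    utr5[(u5 - 7L):u5] <- kz
    utr3 <- .sampleChain(bg, u3)

    ## assemble the sense unit and record CDS segments / introns (unit coords)
    unit <- utr5
    segStartCds <- c(1L, brk + 1L)
    segEndCds <- c(brk, cdsLen)
    unitSegs <- matrix(0L, nrow = nintr + 1L, ncol = 2L)
    intrUnit <- matrix(0L, nrow = nintr, ncol = 2L)
    for (si in seq_len(nintr + 1L)) {
      segSeq <- cds[segStartCds[si]:segEndCds[si]]
      unitSegs[si, ] <- c(length(unit) + 1L, length(unit) + length(segSeq))
      unit <- c(unit, segSeq)
      if (si <= nintr) {
        iseq <- .makeIntron(ilens[si], p, bg)
        intrUnit[si, ] <- c(length(unit) + 1L, length(unit) + length(iseq))
        unit <- c(unit, iseq)
      }
    }
    unit <- c(unit, utr3)
    U <- length(unit)

    if (strand == "-") {
      unit <- revcompCodes(unit)
      mir <- function(m) {
        if (!nrow(m)) return(m)
        out <- cbind(U - m[, 2L] + 1L, U - m[, 1L] + 1L)
        out[rev(seq_len(nrow(out))), , drop = FALSE]
      }
      unitSegs <- mir(unitSegs)
      intrUnit <- mir(intrUnit)
    }

    off <- pos
    addPiece(unit)

    gid <- sprintf("g%04d", gi)
    segdf <- data.frame(gene_id = gid, start = unitSegs[, 1L] + off,
                        end = unitSegs[, 2L] + off, phase = 0L)
    segdf$phase <- .segmentPhases(segdf$start, segdf$end, strand)
    genes[[gi]] <- data.frame(gene_id = gid, transcript_id = NA_character_,
                              contig = p$contig, strand = strand,
                              provenance = "reference", complete5 = TRUE,
                              complete3 = TRUE, score = NA_real_, alt = FALSE,
                              stringsAsFactors = FALSE)
    segs[[gi]] <- segdf

    ## transcript exon blocks: unit span minus introns
    txStart <- off + 1L; txEnd <- off + U
    if (nintr > 0L) {
      istart <- intrUnit[, 1L] + off; iend <- intrUnit[, 2L] + off
      exs <- c(txStart, iend + 1L); exe <- c(istart - 1L, txEnd)
    } else { exs <- txStart; exe <- txEnd }
    geneInfo[[gi]] <- list(gid = gid, strand = strand, exs = exs, exe = exe,
                           cds_start = min(segdf$start), cds_end = max(segdf$end),
                           tx_start = txStart, tx_end = txEnd)
  }
  gap <- .clipInt(rlnorm(1, p$gap_meanlog, p$gap_sdlog), p$gap_range)
  addPiece(.sampleChain(bg, gap))

  contigCodes <- unlist(pieces, use.names = FALSE)
  if (!is.na(p$contig_len)) {
    if (length(contigCodes) > p$contig_len)
      stop("genes do not fit in contig_len = ", p$contig_len,
           " (need ", length(contigCodes), " nt)")
    contigCodes <- c(contigCodes,
                     .sampleChain(bg, p$contig_len - length(contigCodes)))
  }
  genome <- Biostrings::DNAStringSet(setNames(decodeDNA(contigCodes), p$contig))
  truth <- newGeneSet(do.call(rbind, genes), do.call(rbind, segs))

  ## ---- corruption assignment -------------------------------------------
  lab <- data.frame(gene_id = vapply(geneInfo, `[[`, "", "gid"),
                    corruption = "none", stringsAsFactors = FALSE)
  free <- seq_len(n)
  pickN <- function(k) { k <- min(k, length(free)); s <- if (k > 0) sample(free, k) else integer(); free <<- setdiff(free, s); s }
  unexpr <- pickN(round(p$frac_unexpressed * n))
  lab$corruption[unexpr] <- "unexpressed"
  trunc5 <- pickN(round(p$frac_truncated5 * n))
  lab$corruption[trunc5] <- "truncated5"
  fpint <- pickN(round(p$frac_fp_intron * n))
  lab$corruption[fpint] <- "fp_intron"

  pickPairs <- function(nPairs, sameStrand) {
    pairs <- list()
    cand <- free[free < n & (free + 1L) %in% free]
    cand <- cand[sample.int(length(cand))]
    for (i in cand) {
      if (length(pairs) >= nPairs) break
      if (!(i %in% free) || !((i + 1L) %in% free)) next
      same <- geneInfo[[i]]$strand == geneInfo[[i + 1L]]$strand
      if (same != sameStrand) next
      pairs[[length(pairs) + 1L]] <- c(i, i + 1L)
      free <<- setdiff(free, c(i, i + 1L))
    }
    pairs
  }
  ssPairs <- pickPairs(round(p$frac_merged_ss * n / 2), TRUE)
  sasPairs <- if (!p$stranded) pickPairs(round(p$frac_merged_sas * n / 2), FALSE)
              else list()
  for (pr in ssPairs) lab$corruption[pr] <- "merged_ss"
  for (pr in sasPairs) lab$corruption[pr] <- "merged_sas"

  ## ---- emit transcripts -------------------------------------------------
  exRows <- list(); strand <- character(); nt <- 0L
  merged <- unlist(c(ssPairs, sasPairs))
  emit <- function(tid, exs, exe, str) {
    nt <<- nt + 1L
    exRows[[nt]] <<- data.frame(transcript_id = tid, contig = p$contig,
                                start = exs, end = exe, stringsAsFactors = FALSE)
    strand[tid] <<- if (!p$stranded) "*" else str
  }
  for (gi in seq_len(n)) {
    if (gi %in% unexpr || gi %in% merged) next
    info <- geneInfo[[gi]]
    exs <- info$exs; exe <- info$exe
    if (gi %in% trunc5) {
      delta <- sample(30:150, 1L)
      if (info$strand == "+") {
        cut <- min(info$cds_start + delta, info$cds_end - 90L)
        keep <- exe >= cut
        exs <- pmax(exs[keep], cut); exe <- exe[keep]
      } else {
        cut <- max(info$cds_end - delta, info$cds_start + 90L)
        keep <- exs <= cut
        exs <- exs[keep]; exe <- pmin(exe[keep], cut)
      }
    }
    if (gi %in% fpint) {
      ## the false intron must fall strictly inside coding sequence, so that
      ## reading through it is stop-free in the true frame
      lens <- pmin(exe, info$cds_end) - pmax(exs, info$cds_start) + 1L
      big <- which(lens >= 240L)
      b <- if (length(big)) big[which.max(lens[big])] else which.max(lens)
      gl <- sample(60:150, 1L)
      lo <- max(exs[b], info$cds_start) + 60L
      hi <- min(exe[b], info$cds_end) - 60L - gl
      if (hi > lo) {
        at <- sample(lo:hi, 1L)
        exs <- c(exs[seq_len(b - 1L)], exs[b], at + gl + 1L,
                 exs[-seq_len(b)][-1L])
        exe <- c(exe[seq_len(b - 1L)], at - 1L, exe[b], exe[-seq_len(b)][-1L])
        o <- order(exs); exs <- exs[o]; exe <- exe[o]
      } else lab$corruption[gi] <- "none"
    }
    emit(sprintf("t%04d", gi), exs, exe, info$strand)
  }
  for (pr in c(ssPairs, sasPairs)) {
    a <- geneInfo[[pr[1]]]; b <- geneInfo[[pr[2]]]
    exs <- c(a$exs, b$exs); exe <- c(a$exe, b$exe)
    if (a$tx_end + 1L <= b$tx_start - 1L) {
      exs <- c(exs, a$tx_end + 1L); exe <- c(exe, b$tx_start - 1L)
    }
    m <- mergeIntervals(exs, exe)
    emit(sprintf("t%04d_%04d", pr[1], pr[2]), m$start, m$end,
         if (a$strand == b$strand) a$strand else "*")
  }

  txa <- transcriptAlignments(do.call(rbind, exRows), strand)
  new("SyntheticTruth", genome = genome, truth = truth, transcripts = txa,
      labels = lab, params = unclass(p),
      generator = list(coding = coding, background = bg,
                       ## expected fitted boundary totals: GT/AG + planted
                       ## consensus + the 2-nt exonic extension
                       donor_signal_width = 4L + nchar(p$donor_consensus),
                       acceptor_signal_width = 4L + nchar(p$acceptor_consensus)))
}

#' Write a synthetic data set to disk
#'
#' Emits genome FASTA, truth GFF3, transcript GTF and the parameters as YAML.
#'
#' @param truth a [SyntheticTruth-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSynthetic <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(truth@genome, file.path(dir, "genome.fa"))
  writeGFF3(truth@truth, file.path(dir, "truth.gff3"))
  writeTranscriptsGTF(truth@transcripts, file.path(dir, "transcripts.gtf"))
  pars <- truth@params
  pars$stop_probs <- as.list(pars$stop_probs)
  yaml::write_yaml(pars, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Write transcript alignments as GTF
#' @param txa a [TranscriptAlignments-class].
#' @param path output file.
#' @export
writeTranscriptsGTF <- function(txa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(txa@tx))) {
    id <- txa@tx$transcript_id[i]
    st <- txa@tx$strand[i]; if (st == "*") st <- "."
    ex <- txa@exons[txa@exons$transcript_id == id, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(paste(ex$contig[j], "synthetic", "exon", ex$start[j], ex$end[j],
                       ".", st, ".",
                       sprintf('transcript_id "%s"; gene_id "%s";', id, id),
                       sep = "\t"), con)
  }
  invisible(path)
}
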