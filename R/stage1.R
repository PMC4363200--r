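## Stage 1: self-training GHMM over virtually spliced transcript sequences.
##
## State topology:
##   begin -> five_prime_utr | kozak_start | noncoding_transcript
##   five_prime_utr -> kozak_start -> cds -> stop_codon
##   stop_codon -> three_prime_utr | middle_utr | end
##   middle_utr -> kozak_start ;  three_prime_utr -> end ; noncoding -> end
## The kozak_start state is a fixed 11-nt window ending at (and including) the
## ATG; the cds state emits the coding body after the ATG up to (not
## including) the stop codon, so its durations are multiples of 3.

.S1_STATES <- c("five_prime_utr", "kozak_start", "cds", "stop_codon",
                "three_prime_utr", "middle_utr", "noncoding_transcript")

#' Splice every transcript of an alignment set
#'
#' @param genome DNAStringSet.
#' @param txa [TranscriptAlignments-class].
#' @return named list (transcript id -> list of 1 or 2 [SplicedTranscript-class],
#'   two for unknown-strand transcripts).
#' @export
spliceAll <- function(genome, txa) {
  ids <- txa@tx$transcript_id
  setNames(lapply(ids, function(id) spliceTranscript(genome, txa, id)), ids)
}

## One "gene observation" feeds training: coding body codes, Kozak window,
## stop codon, flanking UTR codes, genomic span for the overlap filter.
.obsFromOrf <- function(spl, cfg) {
  codes <- spl@codes
  L <- length(codes)
  orf <- longestMetOrf(codes)
  if (is.null(orf) || (orf$end - orf$start + 1L) < cfg$min_candidate_orf)
    return(list(noncoding = list(codes), genes = list(), utr5 = list(),
                utr3 = list(), middle = list()))
  gspan <- range(spl@coordMap[orf$start:orf$end])
  gene <- list(
    cds_len = orf$end - orf$start + 1L,
    body = codes[(orf$start + 3L):(orf$end - 3L)],
    kozak = if (orf$start >= 9L) codes[(orf$start - 8L):(orf$start + 2L)] else NULL,
    stop = decodeDNA(codes[(orf$end - 2L):orf$end]),
    contig = spl@contig, span = gspan)
  list(noncoding = list(), genes = list(gene),
       utr5 = if (orf$start > 1L) list(codes[1:(orf$start - 1L)]) else list(),
       utr3 = if (orf$end < L) list(codes[(orf$end + 1L):L]) else list(),
       middle = list())
}

.obsFromParse <- function(spl, path, cfg) {
  codes <- spl@codes
  out <- list(noncoding = list(), genes = list(), utr5 = list(), utr3 = list(),
              middle = list())
  for (i in seq_len(nrow(path))) {
    st <- path$state[i]; s <- path$start[i]; e <- path$end[i]
    if (st == "noncoding_transcript") out$noncoding <- c(out$noncoding, list(codes[s:e]))
    else if (st == "five_prime_utr") out$utr5 <- c(out$utr5, list(codes[s:e]))
    else if (st == "three_prime_utr") out$utr3 <- c(out$utr3, list(codes[s:e]))
    else if (st == "middle_utr") out$middle <- c(out$middle, list(codes[s:e]))
    else if (st == "kozak_start") {
      ## gene = kozak [s,e] + cds + stop (topology guarantees the next two)
      ce <- path$end[i + 1L]; se <- path$end[i + 2L]
      gspan <- range(spl@coordMap[(e - 2L):se])
      out$genes <- c(out$genes, list(list(
        cds_len = se - (e - 2L) + 1L,
        body = codes[(e + 1L):ce],
        kozak = codes[s:e],
        stop = decodeDNA(codes[(se - 2L):se]),
        contig = spl@contig, span = gspan)))
    }
  }
  out
}

## Excise ORFs >= maxOrf from a UTR example; returns the remaining fragments.
.exciseUtrOrfs <- function(codes, maxOrf) {
  orfs <- findOrfs(codes)
  orfs <- orfs[orfs$has_stop & (orfs$end - orfs$start + 1L) >= maxOrf, , drop = FALSE]
  if (!nrow(orfs)) return(list(codes))
  cut <- mergeIntervals(orfs$start, orfs$end)
  frags <- list(); prev <- 1L
  for (i in seq_len(nrow(cut))) {
    if (cut$start[i] > prev) frags <- c(frags, list(codes[prev:(cut$start[i] - 1L)]))
    prev <- cut$end[i] + 1L
  }
  if (prev <= length(codes)) frags <- c(frags, list(codes[prev:length(codes)]))
  frags[lengths(frags) >= 5L]
}

#' Build the stage-1 training set
#'
#' Applies the self-training restrictions: coding examples must be at least
#' `min_cds_train` nucleotides (600); ORFs of at least `max_utr_orf` (300) are
#' excised from UTR examples; of genomically overlapping candidate genes only
#' the longest is kept.
#'
#' @param obsList list of per-transcript observation lists (internal format;
#'   produced from longest ORFs at seeding or from parses at retraining).
#' @param cfg a [sporeCallConfig()].
#' @return a list of class `Stage1TrainingSet`.
#' @keywords internal
.buildTrainingSet <- function(obsList, cfg) {
  genes <- do.call(c, lapply(obsList, `[[`, "genes"))
  utr5 <- do.call(c, lapply(obsList, `[[`, "utr5"))
  utr3 <- do.call(c, lapply(obsList, `[[`, "utr3"))
  middle <- do.call(c, lapply(obsList, `[[`, "middle"))
  noncoding <- do.call(c, lapply(obsList, `[[`, "noncoding"))

  ## overlap filter: longest kept
  keep <- rep(TRUE, length(genes))
  if (length(genes) > 1L) {
    lens <- vapply(genes, `[[`, 0L, "cds_len")
    ord <- order(-lens)
    taken <- list()
    for (i in ord) {
      g <- genes[[i]]
      clash <- any(vapply(taken, function(t)
        t$contig == g$contig && t$span[1] <= g$span[2] && g$span[1] <= t$span[2],
        TRUE))
      if (clash) keep[i] <- FALSE else taken <- c(taken, list(g))
    }
  }
  genes <- genes[keep]
  cdsGenes <- genes[vapply(genes, `[[`, 0L, "cds_len") >= cfg$min_cds_train]

  utr5 <- do.call(c, lapply(utr5, .exciseUtrOrfs, maxOrf = cfg$max_utr_orf))
  utr3 <- do.call(c, lapply(utr3, .exciseUtrOrfs, maxOrf = cfg$max_utr_orf))
  middle <- do.call(c, lapply(middle, .exciseUtrOrfs, maxOrf = cfg$max_utr_orf))

  nGenesPerTx <- vapply(obsList, function(o) length(o$genes), 0L)
  ts <- list(
    cds_body = lapply(cdsGenes, `[[`, "body"),
    kozak = Filter(Negate(is.null), lapply(cdsGenes, `[[`, "kozak")),
    stops = vapply(cdsGenes, `[[`, "", "stop"),
    utr5 = utr5, utr3 = utr3, middle = middle, noncoding = noncoding,
    dur = list(
      cds_body = vapply(genes, function(g) g$cds_len - 6L, 0L),
      utr5 = lengths(utr5), utr3 = lengths(utr3),
      middle = lengths(middle), noncoding = lengths(noncoding)),
    counts = list(
      n_tx = length(obsList),
      n_noncoding = sum(nGenesPerTx == 0L),
      n_begin_utr5 = sum(vapply(obsList, function(o) length(o$utr5) > 0L, TRUE)),
      n_begin_kozak = sum(nGenesPerTx > 0L &
                          vapply(obsList, function(o) length(o$utr5) == 0L, TRUE)),
      n_stop_middle = sum(pmax(nGenesPerTx - 1L, 0L)),
      n_stop_utr3 = sum(vapply(obsList, function(o) length(o$utr3) > 0L, TRUE)),
      n_stop_end = sum(nGenesPerTx > 0L &
                       vapply(obsList, function(o) length(o$utr3) == 0L, TRUE))
    ))
  class(ts) <- c("Stage1TrainingSet", "list")
  if (!length(ts$cds_body))
    stop("training failure: no coding examples of >= ", cfg$min_cds_train,
         " nt survive filtering; more transcript data is needed")
  ts
}

#' Seed a training set from the longest ORF of each spliced transcript
#'
#' @param spliced list of [SplicedTranscript-class] (one orientation each; for
#'   unknown-strand transcripts the orientation with the longer
#'   methionine-initiated ORF is used).
#' @param cfg a [sporeCallConfig()].
#' @return a `Stage1TrainingSet`.
#' @export
seedTrainingSet <- function(spliced, cfg = sporeCallConfig()) {
  .buildTrainingSet(lapply(spliced, .obsFromOrf, cfg = cfg), cfg)
}

## Pick one orientation per transcript for seeding: for unknown strands, the
## one carrying the longer longest-Met-ORF (ties: forward).
.seedOrientation <- function(splicedAll) {
  lapply(splicedAll, function(sps) {
    if (length(sps) == 1L) return(sps[[1L]])
    lens <- vapply(sps, function(sp) {
      orf <- longestMetOrf(sp@codes)
      if (is.null(orf)) 0L else orf$end - orf$start + 1L
    }, 0L)
    sps[[which.max(lens)]]
  })
}

## Largest Markov order k' <= k with at least quota * 4^k' training events.
.effectiveOrder <- function(nEvents, k, quota, periodic = FALSE, what = "") {
  per <- nEvents / if (periodic) 3 else 1
  kk <- k
  while (kk > 0L && per < quota * 4^kk) kk <- kk - 1L
  if (kk < k)
    warning("order reduced from ", k, " to ", kk, " for ", what,
            " (", nEvents, " training events)", call. = FALSE)
  kk
}

#' Train the stage-1 transcript-space GHMM
#'
#' Coding sequence: fifth-order three-periodic Markov chain; UTRs (5', 3' and
#' middle) and non-coding transcripts: fifth-order non-periodic chains (one
#' shared UTR table by default); translation start: second-order weighted
#' array matrix over 11 nt ending at the ATG; durations: smoothed empirical.
#'
#' @param ts a `Stage1TrainingSet` (see [seedTrainingSet()]).
#' @param cfg a [sporeCallConfig()].
#' @return a [Stage1Model-class].
#' @export
trainStage1 <- function(ts, cfg = sporeCallConfig()) {
  pc <- cfg$pseudocount; nf <- cfg$n_floor_log
  bw <- if (is.na(cfg$duration_bandwidth)) NA else cfg$duration_bandwidth

  kCds <- .effectiveOrder(sum(lengths(ts$cds_body)), cfg$cds_order,
                          cfg$order_reduce_quota, periodic = TRUE, what = "cds")
  cdsEm <- trainMarkov(ts$cds_body, order = kCds, periodic = TRUE,
                       pseudocount = pc, phases = 0L, nFloorLog = nf)

  utrPool <- if (cfg$utr_shared) c(ts$utr5, ts$utr3, ts$middle) else NULL
  mkUtr <- function(seqs, what) {
    if (!length(seqs)) seqs <- list(encodeDNA("ACGT"))
    k <- .effectiveOrder(sum(lengths(seqs)), cfg$utr_order,
                         cfg$order_reduce_quota, what = what)
    trainMarkov(seqs, order = k, pseudocount = pc, nFloorLog = nf)
  }
  utrEm <- mkUtr(if (cfg$utr_shared) utrPool else ts$utr5, "utr")
  utr3Em <- if (cfg$utr_shared) utrEm else mkUtr(ts$utr3, "utr3")
  ncEm <- mkUtr(ts$noncoding, "noncoding")

  if (!length(ts$kozak))
    stop("training failure: no Kozak windows (all ORFs start within 8 nt of ",
         "their transcript start)")
  kozakEm <- trainWAM(ts$kozak, order = cfg$kozak_order, pseudocount = pc,
                      nFloorLog = nf, backoffAlpha = cfg$wam_backoff)
  stopCounts <- table(factor(ts$stops, levels = .STOP_CODONS)) + 1
  stopEm <- motifEmission(.STOP_CODONS, as.numeric(stopCounts))

  mkDur <- function(lens, step = 1L, lowTo = NULL, tailCap = NA) {
    if (!length(lens)) lens <- c(60L, 120L, 240L)
    sup <- range(lens)
    if (!is.null(lowTo)) sup[1] <- min(sup[1], lowTo)
    smoothDurations(lens, bandwidth = bw, support = sup, step = step,
                    floor = cfg$duration_floor, tailCap = tailCap)
  }
  minBody <- cfg$min_cds_len - 6L
  minBody <- minBody - (minBody %% 3L)
  durs <- list(
    five_prime_utr = mkDur(ts$dur$utr5, lowTo = 1L),
    kozak_start = fixedDuration(cfg$kozak_width),
    cds = mkDur(ts$dur$cds_body, step = 3L, lowTo = minBody, tailCap = 200L),
    stop_codon = fixedDuration(3L),
    three_prime_utr = mkDur(ts$dur$utr3, lowTo = 1L),
    middle_utr = mkDur(if (length(ts$dur$middle)) ts$dur$middle
                       else c(ts$dur$utr5, ts$dur$utr3), lowTo = 1L),
    noncoding_transcript = mkDur(ts$dur$noncoding, lowTo = 30L, tailCap = -1L))

  cn <- ts$counts
  ncPrior <- max((cn$n_noncoding + 1) / (cn$n_tx + 2), cfg$noncoding_prior_floor)
  bu <- cn$n_begin_utr5 + 1; bk <- cn$n_begin_kozak + 1
  begin <- c(five_prime_utr = (1 - ncPrior) * bu / (bu + bk),
             kozak_start = (1 - ncPrior) * bk / (bu + bk),
             noncoding_transcript = ncPrior)
  s3 <- cn$n_stop_utr3 + 1; sm <- cn$n_stop_middle + 1; se <- cn$n_stop_end + 1
  tr <- matrix(0, 7, 7, dimnames = list(.S1_STATES, .S1_STATES))
  tr["five_prime_utr", "kozak_start"] <- 1
  tr["kozak_start", "cds"] <- 1
  tr["cds", "stop_codon"] <- 1
  tr["stop_codon", "three_prime_utr"] <- s3 / (s3 + sm + se)
  tr["stop_codon", "middle_utr"] <- sm / (s3 + sm + se)
  tr["middle_utr", "kozak_start"] <- 1
  end <- c(three_prime_utr = 1, noncoding_transcript = 1,
           stop_codon = se / (s3 + sm + se))

  spec <- ghmmSpec(.S1_STATES, tr, begin, end,
                   emissions = list(five_prime_utr = utrEm, kozak_start = kozakEm,
                                    cds = cdsEm, stop_codon = stopEm,
                                    three_prime_utr = utr3Em,
                                    middle_utr = utrEm,
                                    noncoding_transcript = ncEm),
                   durations = durs, entryPhase = c(cds = 0L))
  new("Stage1Model", spec = spec, config = unclass(cfg),
      trainingSizes = length(ts$cds_body))
}

## Hard ATG requirement for the translation-start window: the WAM softly
## prefers ATG but the gene-model invariant (first codon is ATG) must hold
## structurally, so windows not ending in ATG are forbidden outright.
.kozakAtgPenalty <- function(codes, width) {
  L <- length(codes)
  v <- rep(.NEG_INF, L)
  smax <- L - width + 1L
  if (smax >= 1L) {
    s <- seq_len(smax)
    ok <- codes[s + width - 3L] == 1L & codes[s + width - 2L] == 4L &
      codes[s + width - 1L] == 3L
    v[s][ok] <- 0
  }
  v
}

## In-frame stop-codon exclusion penalty for the cds state: an L x 3 matrix
## forbidding position j for start class (j-1) mod 3 when a stop codon starts
## at j (codon starts satisfy (j - s) mod 3 == 0).
.cdsStopPenalty <- function(codes) {
  L <- length(codes)
  pm <- matrix(0, nrow = L, ncol = 3L)
  stops <- which(stopCodonStarts(codes))
  if (length(stops)) pm[cbind(stops, (stops - 1L) %% 3L + 1L)] <- .NEG_INF
  pm
}

## Decode one spliced transcript; returns list(parse, genes data) or NULL.
.decodeTranscript <- function(model, spl, forbidNoncoding = FALSE) {
  spec <- model@spec
  if (forbidNoncoding) {
    bg <- spec@begin
    bg["noncoding_transcript"] <- 0
    if (sum(bg) == 0) return(NULL)
    spec@begin <- bg / sum(bg)
  }
  pen <- list(cds = .cdsStopPenalty(spl@codes),
              kozak_start = .kozakAtgPenalty(spl@codes,
                                             spec@durations$kozak_start@fixedLength))
  viterbiDecode(spec, spl@codes, penalties = pen)
}

## Score of one predicted gene: log-odds of its kozak/cds/stop segments
## (emissions + durations) against the same span emitted by the UTR chain.
## Raw path log-probabilities scale with length and would rank short spurious
## genes above long real ones; the log-odds is length-stable.
.geneScore <- function(spec, codes, path, i, pen) {
  sc <- 0
  for (j in i:(i + 2L)) {
    st <- path$state[j]
    sc <- sc + .segmentScore(spec, st, codes, path$start[j], path$end[j], pen) +
      durationLogProb(spec@durations[[st]], path$end[j] - path$start[j] + 1L)
  }
  sc - .segmentScore(spec, "five_prime_utr", codes, path$start[i],
                     path$end[i + 2L], NULL)
}

## Extract gene models from one decoded transcript parse.
.genesFromParse <- function(model, spl, parse, provenance) {
  path <- parse$path
  idx <- which(path$state == "kozak_start")
  if (!length(idx)) return(NULL)
  pen <- list(cds = .cdsStopPenalty(spl@codes))
  genes <- list(); segs <- list()
  for (gi in seq_along(idx)) {
    i <- idx[gi]
    tstart <- path$end[i] - 2L          # ATG start (kozak ends at ATG)
    tend <- path$end[i + 2L]            # stop codon end
    lifted <- liftToGenome(spl, tstart, tend)
    gid <- sprintf("%s.%s.%d", spl@transcriptId, spl@strandUsed, gi)
    genes[[gi]] <- data.frame(
      gene_id = gid, transcript_id = spl@transcriptId, contig = spl@contig,
      strand = spl@strandUsed, provenance = provenance,
      complete5 = TRUE, complete3 = TRUE,
      score = .geneScore(model@spec, spl@codes, path, i, pen),
      alt = FALSE, stringsAsFactors = FALSE)
    segs[[gi]] <- data.frame(gene_id = gid, start = lifted$start,
                             end = lifted$end,
                             phase = .segmentPhases(lifted$start, lifted$end,
                                                    spl@strandUsed))
  }
  list(genes = do.call(rbind, genes), segs = do.call(rbind, segs))
}

#' Predict genes from spliced transcripts (stage 1)
#'
#' One Viterbi parse per oriented transcript; each kozak -> cds -> stop run
#' becomes a gene, lifted back to the genome with introns re-inserted exactly
#' at the evidenced introns.  Unknown-strand transcripts are decoded in both
#' orientations and the higher-scoring parse kept (ties: forward).
#'
#' @param model a [Stage1Model-class].
#' @param splicedAll output of [spliceAll()].
#' @param provenance provenance label for the produced genes.
#' @return list(genes = [GeneSet-class], parses = per-transcript parse info).
#' @export
predictStage1 <- function(model, splicedAll, provenance = "stage1") {
  genes <- list(); segs <- list(); parses <- list()
  for (id in names(splicedAll)) {
    sps <- splicedAll[[id]]
    dec <- lapply(sps, function(sp) .decodeTranscript(model, sp))
    okv <- vapply(dec, function(d) isTRUE(d$ok), TRUE)
    if (!any(okv)) stop("internal error: no parse for transcript ", id)
    pick <- if (length(dec) == 1L) 1L else {
      lp <- vapply(dec, function(d) if (isTRUE(d$ok)) d$logprob else -Inf, 0)
      if (lp[1] >= lp[2]) 1L else 2L      # ties: forward
    }
    spl <- sps[[pick]]; parse <- dec[[pick]]
    g <- .genesFromParse(model, spl, parse, provenance)
    parses[[id]] <- list(spliced = spl, path = parse$path,
                         logprob = parse$logprob,
                         n_genes = sum(parse$path$state == "kozak_start"))
    if (!is.null(g)) { genes <- c(genes, list(g$genes)); segs <- c(segs, list(g$segs)) }
  }
  gs <- if (length(genes)) newGeneSet(do.call(rbind, genes), do.call(rbind, segs))
        else emptyGeneSet()
  list(genes = gs, parses = parses)
}

#' Self-train the stage-1 model
#'
#' Parameters are first estimated from the longest methionine-initiated ORF in
#' each transcript; the GHMM is then successively run and retrained twice
#' (regardless of convergence), with the training-set restrictions reapplied
#' at each round.
#'
#' @param genome DNAStringSet.
#' @param txa [TranscriptAlignments-class].
#' @param cfg a [sporeCallConfig()].
#' @return list(model = [Stage1Model-class], prediction = final
#'   [predictStage1()] output, seed_genes = the longest-ORF baseline
#'   [GeneSet-class], training_sizes = coding examples per round).
#' @export
selfTrain <- function(genome, txa, cfg = sporeCallConfig()) {
  splicedAll <- spliceAll(genome, txa)
  seedSpl <- .seedOrientation(splicedAll)
  ts <- seedTrainingSet(seedSpl, cfg)
  sizes <- length(ts$cds_body)
  .vlog(cfg, "stage1 seed training set: ", sizes, " coding examples")
  model <- trainStage1(ts, cfg)

  ## longest-ORF baseline gene set (the pre-GHMM annotation)
  seedGenes <- .seedBaselineGenes(seedSpl, cfg)

  for (iter in seq_len(cfg$retrain_iterations)) {
    pred <- predictStage1(model, splicedAll)
    obs <- lapply(pred$parses, function(p) .obsFromParse(p$spliced, p$path, cfg))
    ts <- .buildTrainingSet(obs, cfg)
    sizes <- c(sizes, length(ts$cds_body))
    .vlog(cfg, "stage1 retrain ", iter, ": ", length(ts$cds_body),
          " coding examples")
    model <- trainStage1(ts, cfg)
  }
  model@trainingSizes <- as.integer(sizes)
  prediction <- predictStage1(model, splicedAll)
  list(model = model, prediction = prediction, seed_genes = seedGenes,
       training_sizes = sizes, spliced = splicedAll)
}

## The longest-ORF-per-transcript annotation used as the self-training seed,
## expressed as gene models for staged accuracy accounting.
.seedBaselineGenes <- function(seedSpl, cfg) {
  genes <- list(); segs <- list(); n <- 0L
  for (spl in seedSpl) {
    orf <- longestMetOrf(spl@codes)
    if (is.null(orf) || (orf$end - orf$start + 1L) < cfg$min_candidate_orf) next
    lifted <- liftToGenome(spl, orf$start, orf$end)
    n <- n + 1L
    gid <- sprintf("seed.%s", spl@transcriptId)
    genes[[n]] <- data.frame(gene_id = gid, transcript_id = spl@transcriptId,
                             contig = spl@contig, strand = spl@strandUsed,
                             provenance = "seed", complete5 = TRUE,
                             complete3 = TRUE, score = NA_real_, alt = FALSE,
                             stringsAsFactors = FALSE)
    segs[[n]] <- data.frame(gene_id = gid, start = lifted$start, end = lifted$end,
                            phase = .segmentPhases(lifted$start, lifted$end,
                                                   spl@strandUsed))
  }
  if (!n) return(emptyGeneSet())
  newGeneSet(do.call(rbind, genes), do.call(rbind, segs))
}
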