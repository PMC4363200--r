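## Shared fixtures and helpers.  Expensive objects (synthetic genomes, trained
## pipelines) are built once per session and memoised here.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, suppressWarnings(force(expr)), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

## a small clean synthetic world used across test files
cleanWorld <- function() fixture("cleanWorld", {
  generateSynthetic(synthParams(n_genes = 30, seed = 101))
})

## a trained stage-1 model + prediction on the clean world
cleanStage1 <- function() fixture("cleanStage1", {
  st <- cleanWorld()
  selfTrain(st@genome, st@transcripts, sporeCallConfig())
})

## full pipeline on the clean world
cleanRun <- function() fixture("cleanRun", {
  st <- cleanWorld()
  runPipeline(st@genome, st@transcripts, sporeCallConfig())
})

## random GHMM instance generator for decoder/oracle comparisons
randomGhmm <- function(nStates) {
  states <- paste0("s", seq_len(nStates))
  tr <- matrix(runif(nStates^2), nStates, nStates,
               dimnames = list(states, states))
  tr[matrix(runif(nStates^2) < 0.3, nStates, nStates)] <- 0
  endp <- runif(nStates, 0.01, 0.3)
  rs <- rowSums(tr)
  scale <- (1 - endp) / pmax(rs, 1e-12)
  tr <- tr * scale
  zero <- rs == 0
  endp[zero] <- 1
  tr[zero, ] <- 0
  bg <- runif(nStates); bg <- bg / sum(bg)
  ems <- list(); durs <- list()
  ep <- setNames(integer(nStates), states)
  for (i in seq_len(nStates)) {
    kind <- sample(c("mkv0", "mkv1", "mkv2p", "wam", "motif"), 1)
    train <- replicate(4, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                                collapse = ""))
    ems[[states[i]]] <- switch(kind,
      mkv0 = trainMarkov(as.list(train), 0),
      mkv1 = trainMarkov(as.list(train), 1),
      mkv2p = trainMarkov(as.list(train), 2, periodic = TRUE),
      wam = trainWAM(substr(train, 1, 3), order = 1),
      motif = motifEmission(c("TAA", "TAG", "TGA", "ACG", "CCA"), runif(5)))
    if (kind == "mkv2p") ep[states[i]] <- sample(0:2, 1)
    durs[[states[i]]] <- if (kind %in% c("wam", "motif")) fixedDuration(3)
      else smoothDurations(sample(2:6, 8, TRUE), bandwidth = 1, support = c(2, 6))
  }
  ghmmSpec(states, tr, bg, endp, ems, durs, ep)
}

randomPenalties <- function(spec, L) {
  setNames(lapply(spec@states, function(s) {
    v <- numeric(L)
    v[sample(L, 1)] <- if (runif(1) < 0.5) -1e30 else -0.5
    v
  }), spec@states)
}

## exact-structure keys for comparing gene sets
geneKeys <- function(gs) {
  if (!nrow(gs@genes)) return(character())
  vapply(gs@genes$gene_id, function(id) {
    s <- gs@segments[gs@segments$gene_id == id, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    paste(gs@genes$contig[gs@genes$gene_id == id],
          gs@genes$strand[gs@genes$gene_id == id],
          paste(s$start, s$end, sep = "-", collapse = ","))
  }, "")
}

geneLevelSn <- function(pred, truth) {
  ev <- evaluatePredictions(pred, truth)
  ev@table$sensitivity[ev@table$level == "gene"]
}

## build a GeneSet from a compact description list(list(contig, strand,
## segs = matrix/list of c(start, end)), ...)
makeGenes <- function(descr, provenance = "stage1", score = NULL) {
  genes <- list(); segs <- list()
  for (i in seq_along(descr)) {
    d <- descr[[i]]
    gid <- if (!is.null(d$id)) d$id else sprintf("t%03d", i)
    sm <- do.call(rbind, d$segs)
    genes[[i]] <- data.frame(gene_id = gid, transcript_id = NA_character_,
                             contig = d$contig, strand = d$strand,
                             provenance = if (!is.null(d$provenance)) d$provenance else provenance,
                             complete5 = TRUE, complete3 = TRUE,
                             score = if (!is.null(d$score)) d$score else NA_real_,
                             alt = isTRUE(d$alt), stringsAsFactors = FALSE)
    segs[[i]] <- data.frame(gene_id = gid, start = sm[, 1], end = sm[, 2],
                            phase = SporeCall:::.segmentPhases(sm[, 1], sm[, 2],
                                                               d$strand))
  }
  newGeneSet(do.call(rbind, genes), do.call(rbind, segs))
}
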