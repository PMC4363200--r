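test_that("coding training set admits only CDS of at least 600 nt", {
  cfg <- sporeCallConfig()
  ## hand-built spliced transcripts: one ORF of exactly 600 nt, one of 597
  off <- 0L
  mk <- function(cdsLen, id) {
    body <- strrep("GCT", (cdsLen - 6) / 3)
    seq <- paste0(strrep("C", 30), "AAACAAAA", "ATG", body, "TAA", strrep("C", 30))
    cm <- seq_len(nchar(seq)) + off
    off <<- off + nchar(seq) + 100L      # keep candidates genomically disjoint
    new("SplicedTranscript", transcriptId = id, contig = "c1", strandUsed = "+",
        codes = SporeCall:::encodeDNA(seq),
        coordMap = cm,
        evidencedIntrons = data.frame(start = integer(), end = integer()))
  }
  ts <- seedTrainingSet(list(mk(600, "a"), mk(597, "b")), cfg)
  expect_equal(length(ts$cds_body), 1L)            # only the 600-nt CDS
  expect_equal(length(ts$cds_body[[1]]), 600L - 6L)
  ## both still contribute duration samples and flanking UTR examples
  expect_equal(sort(ts$dur$cds_body), c(591L, 594L))
})

test_that("ORFs of at least 300 nt are excised from UTR training examples", {
  orf <- paste0("ATG", strrep("GCA", 98), "TAA")   # 300 nt exactly
  utr <- SporeCall:::encodeDNA(paste0(strrep("C", 40), orf, strrep("T", 40)))
  frags <- SporeCall:::.exciseUtrOrfs(utr, 300L)
  expect_equal(sum(lengths(frags)), 80L)

  orf297 <- paste0("ATG", strrep("GCA", 97), "TAA")
  utr2 <- SporeCall:::encodeDNA(paste0(strrep("C", 40), orf297, strrep("T", 40)))
  frags2 <- SporeCall:::.exciseUtrOrfs(utr2, 300L)
  expect_equal(sum(lengths(frags2)), 80L + 297L)   # 297 < 300: kept intact
})

test_that("of genomically overlapping candidate genes the longer is kept", {
  cfg <- sporeCallConfig()
  gene <- function(len, span) list(cds_len = as.integer(len),
                                   body = rep(1L, len - 6L),
                                   kozak = SporeCall:::encodeDNA("AAACAAAAATG"),
                                   stop = "TAA", contig = "c1", span = span)
  obs <- list(
    list(genes = list(gene(900, c(100, 999))), utr5 = list(), utr3 = list(),
         middle = list(), noncoding = list()),
    list(genes = list(gene(750, c(800, 1549))), utr5 = list(), utr3 = list(),
         middle = list(), noncoding = list()),
    list(genes = list(gene(690, c(2000, 2689))), utr5 = list(), utr3 = list(),
         middle = list(), noncoding = list()))
  ts <- SporeCall:::.buildTrainingSet(obs, cfg)
  expect_equal(sort(vapply(ts$cds_body, length, 0L) + 6L), c(690L, 900L))
})

test_that("self-training runs exactly two retraining rounds", {
  res <- cleanStage1()
  expect_equal(length(res$training_sizes), 1L + sporeCallConfig()$retrain_iterations)
  expect_equal(length(res$training_sizes), 3L)
})

test_that("stage-1 genes are complete reading frames anchored on evidenced introns", {
  st <- cleanWorld()
  res <- cleanStage1()
  genes <- res$prediction$genes
  expect_gt(nrow(genes@genes), 0L)
  introns <- evidencedIntrons(st@genome, st@transcripts)
  ikeys <- paste(introns$start, introns$end)
  for (id in genes@genes$gene_id) {
    s <- geneCdsSeq(st@genome, genes, id)
    expect_equal(nchar(s) %% 3, 0)
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    ## every internal CDS gap coincides exactly with an evidenced intron
    seg <- genes@segments[genes@segments$gene_id == id, ]
    seg <- seg[order(seg$start), ]
    if (nrow(seg) > 1L) {
      gaps <- paste(seg$end[-nrow(seg)] + 1L, seg$start[-1] - 1L)
      expect_true(all(gaps %in% ikeys))
    }
  }
})

test_that("merged same-strand transcripts yield one gene per constituent via the middle UTR", {
  st <- fixture("mergedWorld", generateSynthetic(
    synthParams(n_genes = 30, seed = 201, frac_merged_ss = 0.5)))
  res <- fixture("mergedStage1",
                 selfTrain(st@genome, st@transcripts, sporeCallConfig()))
  mergedTx <- grep("_", st@transcripts@tx$transcript_id, value = TRUE)
  expect_gt(length(mergedTx), 1L)
  for (mt in mergedTx) {
    p <- res$prediction$parses[[mt]]
    nGenes <- sum(p$path$state == "kozak_start")
    nMiddle <- sum(p$path$state == "middle_utr")
    expect_gte(nGenes, 2L)
    ## multi-gene parses use exactly one middle UTR per extra gene
    expect_equal(nGenes, 1L + nMiddle)
  }
})

test_that("a transcript of near-random sequence parses as non-coding", {
  res <- cleanStage1()
  st <- cleanWorld()
  set.seed(500)
  bg <- SporeCall:::.dirichletTables(8, periodic = FALSE)
  codes <- SporeCall:::.sampleChain(bg, 700)
  ## remove any ORF longer than 90 nt so the coding states cannot win
  repeat {
    orf <- longestMetOrf(codes)
    if (is.null(orf) || orf$end - orf$start + 1L < 90L) break
    at <- orf$start + 3L * sample(seq_len((orf$end - orf$start - 2L) %/% 3L - 1L), 1L)
    codes[at:(at + 2L)] <- SporeCall:::encodeDNA("TAA")
  }
  spl <- new("SplicedTranscript", transcriptId = "rnd", contig = "chr1",
             strandUsed = "+", codes = codes,
             coordMap = seq_along(codes),
             evidencedIntrons = data.frame(start = integer(), end = integer()))
  dec <- SporeCall:::.decodeTranscript(res$model, spl)
  expect_true(dec$ok)
  expect_equal(dec$path$state, "noncoding_transcript")
})

test_that("gene-level sensitivity does not degrade across self-training rounds", {
  st <- cleanWorld()
  splicedAll <- spliceAll(st@genome, st@transcripts)
  seedSpl <- SporeCall:::.seedOrientation(splicedAll)
  cfg <- sporeCallConfig()
  suppressWarnings({
    ts <- seedTrainingSet(seedSpl, cfg)
    model <- trainStage1(ts, cfg)
    sn <- geneLevelSn(SporeCall:::.seedBaselineGenes(seedSpl, cfg), st@truth)
    for (i in 1:2) {
      pred <- predictStage1(model, splicedAll)
      sn <- c(sn, geneLevelSn(pred$genes, st@truth))
      obs <- lapply(pred$parses, function(p)
        SporeCall:::.obsFromParse(p$spliced, p$path, cfg))
      model <- trainStage1(SporeCall:::.buildTrainingSet(obs, cfg), cfg)
    }
    sn <- c(sn, geneLevelSn(predictStage1(model, splicedAll)$genes, st@truth))
  })
  expect_true(all(diff(sn) >= 0))
})
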