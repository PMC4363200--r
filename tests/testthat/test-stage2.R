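stage2World <- function() fixture("stage2World", {
  st <- cleanWorld()
  cfg <- sporeCallConfig()
  s1 <- cleanStage1()
  list(st = st, cfg = cfg, s1 = s1,
       sel = selectRegions(s1$prediction, st@transcripts, st@genome, cfg),
       cons = buildConstraints(st@transcripts, st@genome, cfg),
       m2 = trainStage2(s1$prediction$genes, s1$model, st@genome,
                        st@transcripts, cfg))
})

test_that("maximum intron length follows the 1.1x rule with the 5000 cap", {
  cfg <- sporeCallConfig()
  expect_equal(maxIntronLength(c(400, 1000), cfg), 1100L)
  expect_equal(maxIntronLength(4800, cfg), 5000L)
  expect_equal(maxIntronLength(4545, cfg), 5000L)   # 1.1x just over the cap
  expect_equal(maxIntronLength(4544, cfg), 4999L)   # just under
  expect_equal(maxIntronLength(integer(), cfg), cfg$default_max_intron)
  cfg2 <- sporeCallConfig(disable_intron_cap = TRUE)
  expect_equal(maxIntronLength(9000, cfg2), 9900L)
})

test_that("chi-square boundary fit finds the planted donor signal width", {
  cfg <- sporeCallConfig()
  expect_equal(unname(qchisq(1 - cfg$chi_p, df = 3)), 11.345, tolerance = 1e-4)

  ## synthetic introns: positional signal at donor positions 1..6 only
  set.seed(42)
  mkIntron <- function() {
    len <- sample(60:120, 1)
    x <- sample(1:4, len, replace = TRUE,
                prob = c(0.25, 0.25, 0.25, 0.25))
    x[1:6] <- SporeCall:::encodeDNA("GTAAGT")
    x[(len - 1):len] <- c(1L, 3L)
    x
  }
  introns <- replicate(300, mkIntron(), simplify = FALSE)
  bl <- fitBoundaryLengths(introns, cfg)
  expect_equal(unname(bl["donor"]), 6L + cfg$exon_ext)   # 6 intronic + 2 exonic
  ## the acceptor side carries no signal beyond the AG: minimal length
  expect_equal(unname(bl["acceptor"]), 2L + cfg$exon_ext)

  ## null case: all positions drawn from the interior composition
  null <- replicate(300, {
    x <- sample(1:4, 80, replace = TRUE)
    x
  }, simplify = FALSE)
  bl0 <- fitBoundaryLengths(null, cfg)
  expect_equal(unname(bl0), c(4L, 4L))

  ## below the minimum intron count the defaults apply
  blf <- fitBoundaryLengths(introns[1:49], cfg)
  expect_equal(unname(blf), rep(cfg$default_boundary_intronic + cfg$exon_ext, 2))
  expect_equal(unname(fitBoundaryLengths(introns[1:50], cfg)["donor"]),
               6L + cfg$exon_ext)
})

test_that("boundary lengths use the fit or the documented fallback by intron count", {
  w <- stage2World()
  cfg <- sporeCallConfig()
  introns <- evidencedIntrons(w$st@genome, w$st@transcripts)
  nCanon <- sum(introns$canonical & introns$len >= cfg$min_intron)
  if (nCanon < cfg$min_introns_for_fit) {
    expect_equal(w$m2@donorLength, cfg$default_boundary_intronic + cfg$exon_ext)
  } else {
    expect_lte(abs(w$m2@donorLength - w$st@generator$donor_signal_width), 1L)
  }
  expect_lte(w$m2@donorLength, cfg$boundary_max)
  expect_gte(w$m2@acceptorLength, 4L)
})

test_that("constraint track forbids boundaries under coverage except near transcript ends", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("A", 400)))
  txa <- transcriptAlignments(
    data.frame(transcript_id = "t1", contig = "c1", start = 101L, end = 300L),
    c(t1 = "+"))
  cfg <- sporeCallConfig()
  ct <- buildConstraints(txa, genome, cfg)
  expect_true(ct$c1$fwd[200])          # mid-transcript: forbidden
  expect_false(ct$c1$fwd[130])         # 30 nt from the 5' end: allowed
  expect_false(ct$c1$fwd[150])         # exactly 50 nt from the end: allowed
  expect_true(ct$c1$fwd[151])          # 51 nt in: forbidden
  expect_false(ct$c1$fwd[271])         # within 50 of the 3' end
  expect_true(ct$c1$fwd[250])
  expect_false(any(ct$c1$rev))         # opposite strand unconstrained
  expect_false(ct$c1$fwd[50])          # outside the transcript

  ## unknown strand constrains both strands
  txa2 <- transcriptAlignments(
    data.frame(transcript_id = "t1", contig = "c1", start = 101L, end = 300L),
    c(t1 = "*"))
  ct2 <- buildConstraints(txa2, genome, cfg)
  expect_true(ct2$c1$fwd[200] && ct2$c1$rev[200])
})

test_that("region selection discards single-exon and suspected-incomplete genes", {
  w <- stage2World()
  sel <- w$sel
  expect_setequal(unique(sel$reasons), intersect(unique(sel$reasons),
                  c("single_exon", "suspected_incomplete")))
  ## every single-exon stage-1 gene is discarded
  for (id in sel$kept@genes$gene_id)
    expect_gt(nrow(sel$kept@segments[sel$kept@segments$gene_id == id, ]), 1L)
  ## every discarded locus lies inside some decoding window
  dsp <- SporeCall:::.geneSpans(sel$discarded)
  for (i in seq_len(nrow(dsp)))
    expect_true(any(sel$windows$contig == dsp$contig[i] &
                    sel$windows$start <= dsp$start[i] &
                    sel$windows$end >= dsp$end[i]))
})

test_that("5'-truncated transcripts are flagged as suspected incomplete", {
  st <- fixture("truncWorld", generateSynthetic(
    synthParams(n_genes = 30, seed = 202, frac_truncated5 = 0.3)))
  s1 <- fixture("truncStage1", selfTrain(st@genome, st@transcripts, sporeCallConfig()))
  sel <- fixture("truncSel",
                 selectRegions(s1$prediction, st@transcripts, st@genome,
                               sporeCallConfig()))
  truncated <- which(st@labels$corruption == "truncated5")
  expect_gt(length(truncated), 0L)
  for (i in truncated) {
    tid <- sprintf("t%04d", i)
    ## the stage-1 gene from this truncated transcript, if any, is discarded
    keptFrom <- sel$kept@genes$transcript_id == tid
    expect_false(any(keptFrom, na.rm = TRUE))
  }
})

test_that("a false-positive evidenced intron opens an alternative-splice window", {
  st <- fixture("fpWorld", generateSynthetic(
    synthParams(n_genes = 30, seed = 203, frac_fp_intron = 0.3)))
  s1 <- fixture("fpStage1", selfTrain(st@genome, st@transcripts, sporeCallConfig()))
  sel <- selectRegions(s1$prediction, st@transcripts, st@genome, sporeCallConfig())
  fp <- which(st@labels$corruption == "fp_intron")
  expect_gt(length(fp), 0L)
  sp <- SporeCall:::.geneSpans(st@truth)
  ## the false intron lies inside true coding sequence, so reading through it
  ## is stop-free and the locus must be flagged
  hits <- vapply(fp, function(i) any(
    sel$alt_introns$start >= sp$start[i] & sel$alt_introns$end <= sp$end[i]), TRUE)
  expect_true(all(hits))
})

test_that("stage-2 predictions respect GT..AG, length bounds and the constraint track", {
  w <- stage2World()
  s2 <- predictStage2(w$m2, w$sel, w$cons, w$st@genome, w$cfg)
  expect_gt(nrow(s2@genes), 0L)
  cseq <- as.character(w$st@genome[[1]])
  for (id in s2@genes$gene_id) {
    seg <- s2@segments[s2@segments$gene_id == id, ]
    seg <- seg[order(seg$start), ]
    strand <- s2@genes$strand[s2@genes$gene_id == id]
    if (nrow(seg) > 1L) {
      istart <- seg$end[-nrow(seg)] + 1L
      iend <- seg$start[-1] - 1L
      ilen <- iend - istart + 1L
      expect_true(all(ilen >= w$m2@minIntron & ilen <= w$m2@maxIntron))
      don <- substr(cseq, istart, istart + 1L)
      acc <- substr(cseq, iend - 1L, iend)
      if (strand == "+") {
        expect_true(all(don == "GT") && all(acc == "AG"))
        fb <- w$cons$chr1$fwd
        expect_false(any(fb[istart]) || any(fb[iend]))
      } else {
        expect_true(all(don == "CT") && all(acc == "AC"))
        fb <- w$cons$chr1$rev
        expect_false(any(fb[istart]) || any(fb[iend]))
      }
    }
    ## frame conservation: the spliced CDS translates without internal stops
    s <- geneCdsSeq(w$st@genome, s2, id)
    expect_equal(nchar(s) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("unexpressed genes are recovered ab initio from genome sequence", {
  st <- fixture("unexprWorld", generateSynthetic(
    synthParams(n_genes = 30, seed = 204, frac_unexpressed = 0.2)))
  run <- fixture("unexprRun",
                 runPipeline(st@genome, st@transcripts, sporeCallConfig()))
  unexpr <- st@truth@genes$gene_id[st@labels$corruption == "unexpressed"]
  expect_gt(length(unexpr), 0L)
  tsp <- SporeCall:::.geneSpans(st@truth)
  fsp <- SporeCall:::.geneSpans(run$final)
  recovered <- vapply(unexpr, function(g) {
    t1 <- tsp[tsp$gene_id == g, ]
    hits <- fsp[fsp$contig == t1$contig & fsp$strand == t1$strand &
                fsp$start <= t1$end & t1$start <= fsp$end, , drop = FALSE]
    if (!nrow(hits)) return(FALSE)
    any(vapply(hits$gene_id, function(h) {
      seg <- run$final@segments[run$final@segments$gene_id == h, ]
      tseg <- st@truth@segments[st@truth@segments$gene_id == g, ]
      ov <- 0L
      for (a in seq_len(nrow(seg))) for (b in seq_len(nrow(tseg)))
        ov <- ov + max(0L, min(seg$end[a], tseg$end[b]) -
                         max(seg$start[a], tseg$start[b]) + 1L)
      ov >= 0.8 * sum(tseg$end - tseg$start + 1L)
    }, TRUE))
  }, TRUE)
  ## ab initio recovery of most silent genes (paper narrative: stage 2 adds
  ## the genes without transcript coverage)
  expect_gte(mean(recovered), 0.7)
  ## and the recovering predictions carry stage-2 provenance
  expect_true(any(run$final@genes$provenance == "stage2"))
})
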