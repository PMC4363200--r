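## codon-exact CDS lengths: n_aa amino acids + stop codon
aaLen <- function(n_aa) 3L * n_aa + 3L

test_that("merging prefers RNA-seq-supported stage-1 genes on same-strand overlap", {
  s1 <- makeGenes(list(
    list(id = "a", contig = "c1", strand = "+", segs = list(c(100, 400), c(480, 700)))),
    provenance = "stage1")
  s2 <- makeGenes(list(
    list(id = "b", contig = "c1", strand = "+", segs = list(c(150, 700))),
    list(id = "c", contig = "c1", strand = "-", segs = list(c(100, 700))),
    list(id = "d", contig = "c1", strand = "+", segs = list(c(900, 1200)))),
    provenance = "stage2")
  out <- combinePredictions(s1, s2)
  prov <- out@genes$provenance
  expect_equal(sum(prov == "stage1"), 1L)
  expect_equal(sum(prov == "stage2"), 2L)  # opposite strand + disjoint kept
  expect_false("150-700" %in% vapply(out@genes$gene_id, function(id) {
    s <- out@segments[out@segments$gene_id == id, ]
    paste(min(s$start), max(s$end), sep = "-")
  }, ""))
  ## ids re-assigned deterministically in genomic order
  expect_true(all(grepl("^SC_\\d{5}$", out@genes$gene_id)))
})

test_that("an alternative-splice stage-2 variant survives merging for arbitration", {
  s1 <- makeGenes(list(
    list(id = "a", contig = "c1", strand = "+",
         segs = list(c(100, 400), c(480, 700)), score = 50)), provenance = "stage1")
  s2alt <- makeGenes(list(
    list(id = "b", contig = "c1", strand = "+", segs = list(c(100, 700)),
         alt = TRUE, score = 10)), provenance = "stage2")
  out <- combinePredictions(s1, s2alt)
  expect_equal(nrow(out@genes), 2L)
})

test_that("genes translating to fewer than 30 amino acids are removed", {
  gs <- makeGenes(list(
    list(id = "s29", contig = "c1", strand = "+", segs = list(c(1, aaLen(29)))),
    list(id = "s30", contig = "c1", strand = "+", segs = list(c(200, 200 + aaLen(30) - 1))),
    list(id = "s31", contig = "c1", strand = "+", segs = list(c(400, 400 + aaLen(31) - 1)))))
  out <- filterShort(gs)
  expect_setequal(out@genes$gene_id, c("s30", "s31"))
  expect_equal(nrow(filterShort(emptyGeneSet())@genes), 0L)
})

test_that("splice variants need a unique intron or 10 unique amino acids", {
  base <- list(c(100, 400), c(500, 802))
  ## variant differing only by 5 aa at the N terminus, same introns: removed
  v5aa <- list(c(115, 400), c(500, 802))
  gs <- makeGenes(list(
    list(id = "main", contig = "c1", strand = "+", segs = base, score = 100),
    list(id = "v5", contig = "c1", strand = "+", segs = v5aa, score = 50)))
  expect_equal(filterVariants(gs)@genes$gene_id, "main")

  ## variant differing by 10 aa (30 nt) at the N terminus: kept
  v10aa <- list(c(70, 400), c(500, 802))
  gs10 <- makeGenes(list(
    list(id = "main", contig = "c1", strand = "+", segs = base, score = 100),
    list(id = "v10", contig = "c1", strand = "+", segs = v10aa, score = 50)))
  expect_setequal(filterVariants(gs10)@genes$gene_id, c("main", "v10"))

  ## variant with 9 unique aa (27 nt): removed at the threshold boundary
  v9aa <- list(c(73, 400), c(500, 802))
  gs9 <- makeGenes(list(
    list(id = "main", contig = "c1", strand = "+", segs = base, score = 100),
    list(id = "v9", contig = "c1", strand = "+", segs = v9aa, score = 50)))
  expect_equal(filterVariants(gs9)@genes$gene_id, "main")

  ## a retained-intron variant brings a unique intron: kept
  vIntron <- list(c(100, 400), c(500, 600), c(650, 802))
  gsI <- makeGenes(list(
    list(id = "main", contig = "c1", strand = "+", segs = base, score = 100),
    list(id = "vI", contig = "c1", strand = "+", segs = vIntron, score = 50)))
  expect_setequal(filterVariants(gsI)@genes$gene_id, c("main", "vI"))

  ## a single-variant locus is kept unconditionally
  single <- makeGenes(list(list(id = "only", contig = "c1", strand = "+",
                                segs = base)))
  expect_equal(filterVariants(single)@genes$gene_id, "only")
})

test_that("nested opposite-strand genes are removed at the 20% boundary", {
  big <- list(id = "big", contig = "c1", strand = "+", segs = list(c(1000, 4000)))
  inside <- makeGenes(list(big,
    list(id = "in", contig = "c1", strand = "-", segs = list(c(2000, 2299)))))
  expect_equal(filterNested(inside)@genes$gene_id, "big")

  ## 300-nt CDS with 25% (75 nt) outside the larger gene's span: kept
  part25 <- makeGenes(list(big,
    list(id = "p25", contig = "c1", strand = "-", segs = list(c(3776, 4075)))))
  expect_setequal(filterNested(part25)@genes$gene_id, c("big", "p25"))

  ## exactly 20% outside: kept ("less than 20%" removes)
  part20 <- makeGenes(list(big,
    list(id = "p20", contig = "c1", strand = "-", segs = list(c(3761, 4060)))))
  expect_setequal(filterNested(part20)@genes$gene_id, c("big", "p20"))

  ## one nucleotide less outside (59/300 < 20%): removed
  part19 <- makeGenes(list(big,
    list(id = "p19", contig = "c1", strand = "-", segs = list(c(3760, 4059)))))
  expect_equal(filterNested(part19)@genes$gene_id, "big")

  strict <- makeGenes(list(big,
    list(id = "p15", contig = "c1", strand = "-", segs = list(c(3746, 4045)))))
  expect_equal(filterNested(strict)@genes$gene_id, "big")

  ## equal-span opposite-strand pair: neither is larger, both kept
  tie <- makeGenes(list(
    list(id = "x", contig = "c1", strand = "+", segs = list(c(100, 400))),
    list(id = "y", contig = "c1", strand = "-", segs = list(c(100, 400)))))
  expect_setequal(filterNested(tie)@genes$gene_id, c("x", "y"))
})

test_that("filters are idempotent and only ever shrink the gene set", {
  run <- cleanRun()
  combined <- run$stages$combined
  cfg <- sporeCallConfig()
  f1 <- filterShort(combined, cfg)
  f2 <- filterVariants(f1, cfg)
  f3 <- filterNested(f2, cfg)
  expect_lte(nrow(f1@genes), nrow(combined@genes))
  expect_lte(nrow(f2@genes), nrow(f1@genes))
  expect_lte(nrow(f3@genes), nrow(f2@genes))
  expect_setequal(filterShort(f1, cfg)@genes$gene_id, f1@genes$gene_id)
  expect_setequal(filterVariants(f2, cfg)@genes$gene_id, f2@genes$gene_id)
  expect_setequal(filterNested(f3, cfg)@genes$gene_id, f3@genes$gene_id)
})

test_that("dubious predictions are forced only in uncovered transcripts", {
  st <- cleanWorld()
  s1 <- cleanStage1()
  spliced <- spliceAll(st@genome, st@transcripts)
  ## with the full annotation every transcript is covered: nothing forced
  run <- cleanRun()
  expect_equal(nrow(run$dubious@genes), 0L)

  ## drop all genes overlapping the first transcript: a forced gene appears
  tid <- st@transcripts@tx$transcript_id[1]
  ex <- st@transcripts@exons[st@transcripts@exons$transcript_id == tid, ]
  fsp <- SporeCall:::.geneSpans(run$final)
  away <- fsp$gene_id[!(fsp$start <= max(ex$end) & min(ex$start) <= fsp$end)]
  pruned <- SporeCall:::.subsetGenes(run$final, away)
  dub <- predictDubious(s1$model, spliced, pruned)
  expect_gte(nrow(dub@genes), 1L)
  expect_true(all(dub@genes$provenance == "dubious"))
  expect_true(all(dub@genes$transcript_id %in%
                  st@transcripts@tx$transcript_id))
  ## the forced parse contains at least one complete gene on that transcript
  expect_true(tid %in% dub@genes$transcript_id)
  ## no dubious gene is part of the main annotation
  expect_false(any(geneKeys(dub) %in% geneKeys(pruned)))
})

test_that("fusion report lists transcripts spanning two or more genes in order", {
  genes <- makeGenes(list(
    list(id = "g1", contig = "c1", strand = "+", segs = list(c(100, 400))),
    list(id = "g2", contig = "c1", strand = "+", segs = list(c(600, 900))),
    list(id = "g3", contig = "c1", strand = "-", segs = list(c(1500, 1900)))))
  txa <- transcriptAlignments(
    data.frame(transcript_id = c("tAB", "tC", "tCD"),
               contig = "c1",
               start = c(50L, 1450L, 550L),
               end = c(950L, 1950L, 1950L)),
    c(tAB = "+", tC = "-", tCD = "*"))
  fus <- reportFusions(genes, txa)
  expect_setequal(fus$transcript_id, c("tAB", "tCD"))
  expect_equal(fus$n_constituents[fus$transcript_id == "tAB"], 2L)
  expect_equal(fus$strand_pattern[fus$transcript_id == "tAB"], "++")
  expect_equal(fus$strand_pattern[fus$transcript_id == "tCD"], "+-")
  expect_false("tC" %in% fus$transcript_id)
})
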