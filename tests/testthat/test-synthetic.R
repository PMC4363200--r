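test_that("generation is byte-deterministic under a fixed seed", {
  a <- generateSynthetic(synthParams(n_genes = 12, seed = 42))
  b <- generateSynthetic(synthParams(n_genes = 12, seed = 42))
  expect_identical(as.character(a@genome), as.character(b@genome))
  expect_identical(a@transcripts@exons, b@transcripts@exons)
  expect_identical(a@truth@segments, b@truth@segments)
  c <- generateSynthetic(synthParams(n_genes = 12, seed = 43))
  expect_false(identical(as.character(a@genome), as.character(c@genome)))
})

test_that("every generated gene is a clean reading frame with GT..AG introns", {
  st <- cleanWorld()
  for (id in st@truth@genes$gene_id) {
    s <- geneCdsSeq(st@genome, st@truth, id)
    expect_equal(nchar(s) %% 3, 0)
    expect_equal(substr(s, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
  }
  introns <- evidencedIntrons(st@genome, st@transcripts)
  expect_true(all(introns$canonical))
  expect_true(all(introns$len >= 40 & introns$len <= 200))
})

test_that("with no corruption, transcripts exactly cover genes plus UTRs", {
  st <- cleanWorld()
  expect_true(all(st@labels$corruption == "none"))
  expect_equal(nrow(st@transcripts@tx), nrow(st@truth@genes))
  sp <- SporeCall:::.geneSpans(st@truth)
  for (i in seq_len(nrow(sp))) {
    tid <- sprintf("t%04d", i)
    ex <- st@transcripts@exons[st@transcripts@exons$transcript_id == tid, ]
    expect_lte(min(ex$start), sp$start[i])
    expect_gte(max(ex$end), sp$end[i])
  }
})

test_that("each corruption type is individually switchable and labelled", {
  st <- generateSynthetic(synthParams(n_genes = 40, seed = 9,
                                      frac_unexpressed = 0.2))
  expect_equal(sum(st@labels$corruption == "unexpressed"), 8L)
  expect_equal(nrow(st@transcripts@tx), 32L)

  st <- generateSynthetic(synthParams(n_genes = 40, seed = 9,
                                      frac_truncated5 = 0.2))
  tr <- which(st@labels$corruption == "truncated5")
  expect_equal(length(tr), 8L)
  sp <- SporeCall:::.geneSpans(st@truth)
  for (i in tr) {
    tid <- sprintf("t%04d", i)
    ex <- st@transcripts@exons[st@transcripts@exons$transcript_id == tid, ]
    if (sp$strand[i] == "+") expect_gt(min(ex$start), sp$start[i])
    else expect_lt(max(ex$end), sp$end[i])
  }

  st <- generateSynthetic(synthParams(n_genes = 40, seed = 9,
                                      frac_merged_ss = 0.4))
  merged <- unique(st@labels$corruption)
  expect_true("merged_ss" %in% merged)
  mergedTx <- grep("_", st@transcripts@tx$transcript_id, value = TRUE)
  expect_gt(length(mergedTx), 0L)
  ## a merged transcript spans both constituent genes
  for (mt in mergedTx) {
    gi <- as.integer(strsplit(sub("^t", "", mt), "_")[[1]])
    ex <- st@transcripts@exons[st@transcripts@exons$transcript_id == mt, ]
    expect_lte(min(ex$start), sp$start[gi[1]])
  }
})

test_that("merged-pair counts scale with the requested fraction", {
  counts <- vapply(1:4, function(seed) {
    st <- generateSynthetic(synthParams(n_genes = 100, seed = seed,
                                        frac_merged_ss = 0.2))
    sum(st@labels$corruption == "merged_ss") / 2
  }, 0)
  ## 10 pairs requested; adjacency and strand matching limit the yield, so
  ## allow a generous binomial-style band around the target
  expect_true(all(counts >= 3 & counts <= 10))
})

test_that("unstranded mode erases strand and merges sense-antisense pairs", {
  st <- generateSynthetic(synthParams(n_genes = 40, seed = 10, stranded = FALSE,
                                      frac_merged_sas = 0.4))
  expect_true(all(st@transcripts@tx$strand == "*"))
  expect_gt(sum(st@labels$corruption == "merged_sas"), 0L)
})

test_that("infeasible packing into a fixed contig length is an error", {
  expect_error(generateSynthetic(synthParams(n_genes = 50, seed = 1,
                                             contig_len = 1000L)),
               "do not fit")
})

test_that("synthetic data round-trips through FASTA/GFF3/GTF on disk", {
  st <- generateSynthetic(synthParams(n_genes = 8, seed = 77))
  dir <- withr::local_tempdir()
  writeSynthetic(st, dir)
  g2 <- readGenome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g2), as.character(st@genome))
  t2 <- readGFF3Genes(file.path(dir, "truth.gff3"))
  expect_setequal(unname(geneKeys(t2)), unname(geneKeys(st@truth)))
  x2 <- readTranscripts(file.path(dir, "transcripts.gtf"))
  expect_equal(nrow(x2@exons), nrow(st@transcripts@exons))
  expect_setequal(x2@tx$transcript_id, st@transcripts@tx$transcript_id)
})
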