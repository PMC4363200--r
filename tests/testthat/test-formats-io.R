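test_that("genome FASTA reading folds case, truncates headers, checks alphabet", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), fa)
  g <- readGenome(fa)
  expect_equal(as.character(g[["c1"]]), "ACGT")

  writeLines(c(">c1 some description", "ACGTN"), fa)
  g <- readGenome(fa)
  expect_equal(names(g), "c1")
  expect_equal(as.character(g[["c1"]]), "ACGTN")

  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), fa)
  expect_error(readGenome(fa), "duplicate contig")

  writeLines(c(">c1", "ACRT"), fa)
  expect_error(readGenome(fa), "outside")
})

test_that("GTF exon parsing groups transcripts and maps '.' strand to unknown", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c1", "x", "exon", 11, 15, ".", "+", ".", 'transcript_id "t1";', sep = "\t"),
    paste("c1", "x", "CDS", 1, 5, ".", "+", "0", 'transcript_id "t1";', sep = "\t"),
    paste("c1", "x", "exon", 1, 5, ".", "+", ".", 'transcript_id "t1";', sep = "\t")
  ), gtf)
  txa <- readTranscripts(gtf)
  expect_equal(nrow(txa@tx), 1L)
  ex <- txa@exons
  expect_equal(ex$start, c(1L, 11L))     # sorted despite file order
  expect_equal(ex$end, c(5L, 15L))
  expect_equal(txa@tx$strand, "+")

  writeLines(paste("c1", "x", "exon", 1, 5, ".", ".", ".",
                   'transcript_id "t1";', sep = "\t"), gtf)
  expect_equal(readTranscripts(gtf)@tx$strand, "*")

  writeLines(c(
    paste("c1", "x", "exon", 1, 5, ".", "+", ".", 'transcript_id "t1";', sep = "\t"),
    paste("c2", "x", "exon", 11, 15, ".", "+", ".", 'transcript_id "t1";', sep = "\t")
  ), gtf)
  expect_error(readTranscripts(gtf), "consistency error.*t1")

  writeLines(paste("c1", "x", "exon", 9, 5, ".", "+", ".",
                   'transcript_id "t1";', sep = "\t"), gtf)
  expect_error(readTranscripts(gtf), "format error at line 1")
})

test_that("GFF3 dialect is auto-detected via Parent attributes", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    paste("c1", "x", "exon", 1, 5, ".", "-", ".", "ID=e1;Parent=tx9", sep = "\t"),
    paste("c1", "x", "exon", 11, 15, ".", "-", ".", "ID=e2;Parent=tx9", sep = "\t")
  ), gff)
  txa <- readTranscripts(gff)
  expect_equal(txa@tx$transcript_id, "tx9")
  expect_equal(txa@tx$strand, "-")
  expect_equal(nrow(txa@exons), 2L)
})

test_that("sub-minimum exon gaps are merged as alignment noise", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c1", "x", "exon", 1, 10, ".", "+", ".", 'transcript_id "t1";', sep = "\t"),
    paste("c1", "x", "exon", 14, 30, ".", "+", ".", 'transcript_id "t1";', sep = "\t"),
    paste("c1", "x", "exon", 40, 50, ".", "+", ".", 'transcript_id "t1";', sep = "\t")
  ), gtf)
  txa <- readTranscripts(gtf, minIntron = 4L)
  ex <- txa@exons
  expect_equal(nrow(ex), 2L)          # 3-nt gap merged, 9-nt gap kept
  expect_equal(ex$start, c(1L, 40L))
  expect_equal(ex$end, c(30L, 50L))
})

test_that("GFF3 write -> read round-trips gene structure and provenance", {
  gs <- makeGenes(list(
    list(contig = "c1", strand = "+", segs = list(c(10, 18)), provenance = "stage1"),
    list(contig = "c1", strand = "-", segs = list(c(101, 160), c(201, 262)),
         provenance = "stage2")))
  out <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(gs, out)
  lines <- readLines(out)
  expect_equal(lines[1], "##gff-version 3")
  cdsLines <- grep("\tCDS\t", lines, value = TRUE)
  expect_equal(length(cdsLines), 3L)
  f <- strsplit(cdsLines[1], "\t")[[1]]
  expect_equal(as.integer(f[4:5]), c(10L, 18L))
  expect_equal(f[7], "+"); expect_equal(f[8], "0")

  back <- readGFF3Genes(out)
  expect_equal(sort(geneKeys(back)), sort(geneKeys(gs)))
  expect_setequal(back@genes$provenance, c("stage1", "stage2"))
  ## reverse-strand phases: walk spliced CDS length mod 3 from the 3' segment
  seg <- back@segments[back@segments$gene_id ==
                       back@genes$gene_id[back@genes$strand == "-"], ]
  seg <- seg[order(seg$start), ]
  expect_equal(seg$phase, c((3 - (62 %% 3)) %% 3, 0))
})

test_that("empty gene set writes only the GFF3 header", {
  out <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(emptyGeneSet(), out)
  expect_equal(readLines(out), "##gff-version 3")
})

test_that("configuration round-trips through YAML and rejects bad entries", {
  cfg <- sporeCallConfig(min_intron = 25L)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeConfig(cfg, f)
  cfg2 <- readConfig(f)
  expect_equal(cfg2$min_intron, 25L)
  expect_equal(cfg2$min_cds_train, 600L)
  expect_error(sporeCallConfig(nonsense_key = 1), "unknown configuration")
  expect_error(sporeCallConfig(min_aa = -1), "positive")
})
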