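## Full prediction run: stage 1 self-training -> region selection -> stage 2
## genome decoding -> merge -> filters -> dubious genes and fusion report.

#' Run the whole two-stage prediction pipeline
#'
#' @param genome a DNAStringSet or path to a genome FASTA.
#' @param transcripts a [TranscriptAlignments-class] or path to a GTF/GFF3 of
#'   assembled transcript alignments.
#' @param cfg a [sporeCallConfig()].
#' @param outDir optional output directory; when given, writes
#'   `predictions.gff3`, `dubious.gff3`, `fusions.tsv`, the trained model
#'   dumps and a run log.
#' @return (invisibly) a list with elements `final` (the main annotation
#'   [GeneSet-class]), `dubious`, `fusions`, `stages` (named list of gene sets
#'   after each stage: seed_orf, stage1, stage1_kept, stage2, combined,
#'   final), `stage1_model`, `stage2_model`, `selection` and `log` (character
#'   vector of per-stage counts).
#' @export
runPipeline <- function(genome, transcripts, cfg = sporeCallConfig(),
                        outDir = NULL) {
  if (is.character(genome)) genome <- readGenome(genome)
  txa <- if (is.character(transcripts)) readTranscripts(transcripts) else transcripts
  if (!isTRUE(cfg$stranded) && any(txa@tx$strand != "*")) {
    txa@tx$strand[] <- "*"
  }
  logLines <- character()
  note <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    .vlog(cfg, line)
  }

  note("transcripts: ", nrow(txa@tx), " (unknown strand: ",
       sum(txa@tx$strand == "*"), ")")

  s1 <- selfTrain(genome, txa, cfg)
  note("stage1 training set sizes: ", paste(s1$training_sizes, collapse = " -> "))
  note("longest-ORF seed genes: ", nrow(s1$seed_genes@genes))
  note("stage1 genes: ", nrow(s1$prediction$genes@genes))

  sel <- selectRegions(s1$prediction, txa, genome, cfg)
  note("stage1 kept: ", nrow(sel$kept@genes), "; discarded: ",
       nrow(sel$discarded@genes), " (",
       paste(names(table(sel$reasons)), table(sel$reasons), collapse = ", "),
       ")")
  note("genomic windows: ", nrow(sel$windows), " (alt-splice: ",
       sum(sel$windows$alt), ")")

  constraints <- buildConstraints(txa, genome, cfg)
  s2model <- trainStage2(s1$prediction$genes, s1$model, genome, txa, cfg)
  note("intron model: donor/acceptor ", s2model@donorLength, "/",
       s2model@acceptorLength, " nt, intron length [",
       s2model@minIntron, ", ", s2model@maxIntron, "]")

  s2genes <- predictStage2(s2model, sel, constraints, genome, cfg)
  note("stage2 genes: ", nrow(s2genes@genes))

  combined <- combinePredictions(sel$kept, s2genes)
  note("combined (pre-filter): ", nrow(combined@genes))

  f1 <- filterShort(combined, cfg)
  f2 <- filterVariants(f1, cfg)
  final <- .renameGenes(filterNested(f2, cfg))
  note("after filters (short/variants/nested): ", nrow(f1@genes), "/",
       nrow(f2@genes), "/", nrow(final@genes))

  dubious <- predictDubious(s1$model, s1$spliced, final)
  note("dubious genes: ", nrow(dubious@genes))
  fusions <- reportFusions(final, txa)
  note("suspected fused transcripts: ", nrow(fusions))

  stages <- list(seed_orf = s1$seed_genes,
                 stage1 = s1$prediction$genes,
                 stage1_kept = sel$kept,
                 stage2 = s2genes,
                 combined = combined,
                 final = final)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeGFF3(final, file.path(outDir, "predictions.gff3"))
    writeGFF3(dubious, file.path(outDir, "dubious.gff3"))
    writeFusionReport(fusions, file.path(outDir, "fusions.tsv"))
    writeGhmmSpec(s1$model@spec, file.path(outDir, "stage1_model.txt"))
    writeGhmmSpec(s2model@spec, file.path(outDir, "stage2_model.txt"))
    writeLines(logLines, file.path(outDir, "run.log"))
    if (isTRUE(cfg$verbose)) {
      ## intermediate sets for debugging: the raw stage-1 prediction, the
      ## retained stage-1 subset and the stage-2-only genes
      writeGFF3(s1$prediction$genes, file.path(outDir, "stage1_prefilter.gff3"))
      writeGFF3(sel$kept, file.path(outDir, "stage1_kept.gff3"))
      writeGFF3(s2genes, file.path(outDir, "stage2_only.gff3"))
    }
  }

  invisible(list(final = final, dubious = dubious, fusions = fusions,
                 stages = stages, stage1_model = s1$model,
                 stage2_model = s2model, selection = sel, log = logLines))
}
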