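## Burset-Guigo sensitivity/specificity at nucleotide, exon, intron and gene
## level, in whole-annotation ("full") and high-confidence bounded mode.

.exonKeys <- function(gs) {
  s <- gs@segments
  g <- gs@genes
  if (!nrow(s)) return(character())
  strand <- setNames(g$strand, g$gene_id)
  contig <- setNames(g$contig, g$gene_id)
  paste(contig[s$gene_id], strand[s$gene_id], s$start, s$end)
}

.intronKeys <- function(gs) {
  out <- character()
  g <- gs@genes
  for (id in g$gene_id) {
    s <- gs@segments[gs@segments$gene_id == id, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2L) next
    out <- c(out, paste(g$contig[g$gene_id == id], g$strand[g$gene_id == id],
                        s$end[-nrow(s)] + 1L, s$start[-1] - 1L))
  }
  out
}

.geneKeys <- function(gs) {
  g <- gs@genes
  vapply(g$gene_id, function(id) {
    s <- gs@segments[gs@segments$gene_id == id, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    paste(g$contig[g$gene_id == id], g$strand[g$gene_id == id],
          paste(s$start, s$end, sep = "-", collapse = ","))
  }, "")
}

## coding positions as a GRanges-backed set per (contig, strand)
.cdsRanges <- function(gs) {
  s <- gs@segments
  g <- gs@genes
  if (!nrow(s)) return(GenomicRanges::GRanges())
  strand <- setNames(g$strand, g$gene_id)
  contig <- setNames(g$contig, g$gene_id)
  gr <- GenomicRanges::GRanges(
    seqnames = contig[s$gene_id],
    ranges = IRanges::IRanges(s$start, s$end),
    strand = strand[s$gene_id])
  GenomicRanges::reduce(gr)
}

#' Burset-Guigo evaluation of a prediction against a reference
#'
#' Sensitivity is the proportion of reference features correctly predicted;
#' specificity the proportion of predicted features that are correct.
#' Nucleotide counts are strand-aware coding-base overlaps; exons and introns
#' require exact boundary matches; genes require the identical ordered CDS
#' segment list.  In bounded mode, counting is restricted to the reference
#' gene spans extended by any overlapping predicted gene: predictions entirely
#' outside those regions are excluded (the reference plays the role of a
#' trusted but incomplete high-confidence subset).
#'
#' @param predicted,reference [GeneSet-class]es on the same genome.
#' @param mode "full" or "bounded".
#' @return an [EvaluationReport-class].
#' @export
evaluatePredictions <- function(predicted, reference, mode = c("full", "bounded")) {
  mode <- match.arg(mode)
  predC <- unique(predicted@genes$contig)
  refC <- unique(reference@genes$contig)
  if (length(predC) && length(refC) && !length(intersect(predC, refC)))
    stop("contig mismatch between prediction (", paste(predC, collapse = ","),
         ") and reference (", paste(refC, collapse = ","), ")")

  pred <- predicted
  if (mode == "bounded" && nrow(reference@genes)) {
    rsp <- .geneSpans(reference)
    psp <- .geneSpans(predicted)
    keep <- vapply(seq_len(nrow(psp)), function(i)
      any(rsp$contig == psp$contig[i] & rsp$start <= psp$end[i] &
          psp$start[i] <= rsp$end[i]), TRUE)
    pred <- .subsetGenes(predicted, psp$gene_id[keep])
  }

  predCds <- .cdsRanges(pred)
  refCds <- .cdsRanges(reference)
  ovl <- GenomicRanges::intersect(predCds, refCds)
  ntTP <- sum(IRanges::width(ovl))
  ntPred <- sum(IRanges::width(predCds))
  ntRef <- sum(IRanges::width(refCds))

  exP <- .exonKeys(pred); exR <- .exonKeys(reference)
  inP <- .intronKeys(pred); inR <- .intronKeys(reference)
  gP <- .geneKeys(pred); gR <- .geneKeys(reference)

  mk <- function(level, tpn, refn, predn) data.frame(
    level = level, tp = as.integer(tpn), reference_total = as.integer(refn),
    predicted_total = as.integer(predn),
    sensitivity = if (refn > 0) 100 * tpn / refn else NA_real_,
    specificity = if (predn > 0) 100 * tpn / predn else NA_real_,
    stringsAsFactors = FALSE)

  tb <- rbind(
    mk("nucleotide", ntTP, ntRef, ntPred),
    mk("exon", length(intersect(unique(exP), unique(exR))),
       length(unique(exR)), length(unique(exP))),
    mk("intron", length(intersect(unique(inP), unique(inR))),
       length(unique(inR)), length(unique(inP))),
    mk("gene", length(intersect(unique(gP), unique(gR))),
       length(unique(gR)), length(unique(gP))))
  new("EvaluationReport", mode = mode, table = tb)
}

#' Write an evaluation report as TSV
#' @param report an [EvaluationReport-class].
#' @param path output file.
#' @export
writeEvaluationReport <- function(report, path) {
  write.table(report@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
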