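## Merging of stage-1/stage-2 predictions, the three false-positive filters,
## forced "dubious" predictions, and the merged-transcript (fusion) report.

.geneSpans <- function(gs) {
  g <- gs@genes
  if (!nrow(g)) return(data.frame(gene_id = character(), contig = character(),
                                  strand = character(), start = integer(),
                                  end = integer(), cds_len = integer()))
  s <- gs@segments
  lo <- vapply(g$gene_id, function(id) min(s$start[s$gene_id == id]), 0L)
  hi <- vapply(g$gene_id, function(id) max(s$end[s$gene_id == id]), 0L)
  len <- vapply(g$gene_id, function(id)
    sum(s$end[s$gene_id == id] - s$start[s$gene_id == id] + 1L), 0L)
  data.frame(gene_id = g$gene_id, contig = g$contig, strand = g$strand,
             start = lo, end = hi, cds_len = len, stringsAsFactors = FALSE)
}

## total CDS-nucleotide overlap of gene a's segments with gene b's segments
.cdsOverlapNt <- function(gs, a, b) {
  sa <- gs@segments[gs@segments$gene_id == a, , drop = FALSE]
  sb <- gs@segments[gs@segments$gene_id == b, , drop = FALSE]
  tot <- 0L
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb)))
    tot <- tot + max(0L, min(sa$end[i], sb$end[j]) - max(sa$start[i], sb$start[j]) + 1L)
  tot
}

.geneIntrons <- function(gs, id) {
  s <- gs@segments[gs@segments$gene_id == id, , drop = FALSE]
  s <- s[order(s$start), , drop = FALSE]
  if (nrow(s) < 2L) return(character())
  paste(s$end[-nrow(s)] + 1L, s$start[-1] - 1L, sep = "-")
}

.subsetGenes <- function(gs, ids) {
  newGeneSet(gs@genes[gs@genes$gene_id %in% ids, , drop = FALSE],
             gs@segments[gs@segments$gene_id %in% ids, , drop = FALSE])
}

#' Merge stage-1 and stage-2 predictions
#'
#' Union of the two sets; where a stage-2 gene's CDS overlaps a kept stage-1
#' gene's CDS on the same strand, the stage-1 (RNA-seq supported) gene wins.
#' Stage-2 candidates from alternative-splice windows that differ structurally
#' from every overlapping stage-1 gene are kept as splice variants, to be
#' arbitrated by [filterVariants()].  Gene ids are re-assigned in genomic
#' order.
#'
#' @param keptStage1,stage2Genes [GeneSet-class]es.
#' @return a combined [GeneSet-class].
#' @export
combinePredictions <- function(keptStage1, stage2Genes) {
  both <- newGeneSet(rbind(keptStage1@genes, stage2Genes@genes),
                     rbind(keptStage1@segments, stage2Genes@segments))
  sp <- .geneSpans(both)
  g <- both@genes
  s1ids <- keptStage1@genes$gene_id
  drop <- character()
  structKey <- function(id) {
    seg <- both@segments[both@segments$gene_id == id, , drop = FALSE]
    paste(sort(paste(seg$start, seg$end)), collapse = ",")
  }
  for (id in stage2Genes@genes$gene_id) {
    me <- sp[sp$gene_id == id, ]
    over <- sp$gene_id[sp$gene_id %in% s1ids & sp$contig == me$contig &
                       sp$strand == me$strand &
                       sp$start <= me$end & me$start <= sp$end]
    over <- over[vapply(over, function(o) .cdsOverlapNt(both, id, o) > 0L, TRUE)]
    if (!length(over)) next
    isAlt <- isTRUE(g$alt[g$gene_id == id])
    if (isAlt && !structKey(id) %in% vapply(over, structKey, "")) next
    drop <- c(drop, id)
  }
  res <- .subsetGenes(both, setdiff(g$gene_id, drop))
  .renameGenes(res)
}

.renameGenes <- function(gs, prefix = "SC") {
  g <- gs@genes; s <- gs@segments
  if (!nrow(g)) return(gs)
  sp <- .geneSpans(gs)
  ord <- order(sp$contig, sp$start, sp$end)
  newIds <- setNames(sprintf("%s_%05d", prefix, seq_along(ord)), sp$gene_id[ord])
  g$gene_id <- unname(newIds[g$gene_id])
  s$gene_id <- unname(newIds[s$gene_id])
  newGeneSet(g[order(match(g$gene_id, sort(g$gene_id))), , drop = FALSE],
             s[order(s$gene_id, s$start), , drop = FALSE])
}

#' Remove genes coding for fewer than 30 amino acids
#'
#' @param genes a [GeneSet-class].
#' @param cfg a [sporeCallConfig()] (threshold `min_aa`).
#' @return filtered [GeneSet-class].
#' @export
filterShort <- function(genes, cfg = sporeCallConfig()) {
  sp <- .geneSpans(genes)
  ## CDS includes the stop codon: < min_aa translated amino acids means
  ## spliced CDS < 3 * min_aa + 3 nucleotides
  keep <- sp$gene_id[sp$cds_len >= 3L * cfg$min_aa + 3L]
  .subsetGenes(genes, keep)
}

#' Retain only informative splice variants
#'
#' Variants are grouped by locus (same-strand CDS overlap sharing an intron or
#' at least half the shorter CDS).  The highest-scoring variant of each locus
#' is always kept; any other variant is kept only with at least one intron
#' absent from all kept variants, or at least `variant_min_aa` (10) amino
#' acids outside the union of the kept variants' CDS.
#'
#' @param genes a [GeneSet-class].
#' @param cfg a [sporeCallConfig()].
#' @return filtered [GeneSet-class].
#' @export
filterVariants <- function(genes, cfg = sporeCallConfig()) {
  sp <- .geneSpans(genes)
  n <- nrow(sp)
  if (n < 2L) return(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sp$contig[i] != sp$contig[j] || sp$strand[i] != sp$strand[j]) next
    if (sp$start[i] > sp$end[j] || sp$start[j] > sp$end[i]) next
    ov <- .cdsOverlapNt(genes, sp$gene_id[i], sp$gene_id[j])
    if (ov == 0L) next
    shared <- length(intersect(.geneIntrons(genes, sp$gene_id[i]),
                               .geneIntrons(genes, sp$gene_id[j]))) > 0L
    if (shared || ov >= cfg$variant_overlap_frac * min(sp$cds_len[i], sp$cds_len[j]))
      parent[find(i)] <- find(j)
  }
  grp <- vapply(seq_len(n), find, 0L)
  score <- genes@genes$score[match(sp$gene_id, genes@genes$gene_id)]
  score[is.na(score)] <- -Inf
  keep <- character()
  for (gset in split(seq_len(n), grp)) {
    if (length(gset) == 1L) { keep <- c(keep, sp$gene_id[gset]); next }
    ord <- gset[order(-score[gset], sp$start[gset])]
    keptIds <- sp$gene_id[ord[1]]
    keptIntrons <- .geneIntrons(genes, keptIds)
    keptCds <- genes@segments[genes@segments$gene_id %in% keptIds, , drop = FALSE]
    for (i in ord[-1]) {
      id <- sp$gene_id[i]
      myIntrons <- .geneIntrons(genes, id)
      uniqueIntron <- length(setdiff(myIntrons, keptIntrons)) > 0L
      seg <- genes@segments[genes@segments$gene_id == id, , drop = FALSE]
      covered <- 0L
      for (r in seq_len(nrow(seg))) for (k in seq_len(nrow(keptCds)))
        covered <- covered + max(0L, min(seg$end[r], keptCds$end[k]) -
                                   max(seg$start[r], keptCds$start[k]) + 1L)
      outside <- sum(seg$end - seg$start + 1L) - covered
      if (uniqueIntron || outside >= 3L * cfg$variant_min_aa) {
        keptIds <- c(keptIds, id)
        keptIntrons <- union(keptIntrons, myIntrons)
        keptCds <- rbind(keptCds, seg)
      }
    }
    keep <- c(keep, keptIds)
  }
  .subsetGenes(genes, keep)
}

#' Remove small genes nested in larger opposite-strand genes
#'
#' For each opposite-strand overlapping pair, the smaller gene is removed when
#' less than `nested_frac` (20\%) of its CDS nucleotides lie outside the
#' larger gene's genomic span.  Applied iteratively largest-first; equal-span
#' pairs are both kept.
#'
#' @param genes a [GeneSet-class].
#' @param cfg a [sporeCallConfig()].
#' @return filtered [GeneSet-class].
#' @export
filterNested <- function(genes, cfg = sporeCallConfig()) {
  sp <- .geneSpans(genes)
  if (nrow(sp) < 2L) return(genes)
  spanLen <- sp$end - sp$start + 1L
  ord <- order(-spanLen)
  alive <- rep(TRUE, nrow(sp))
  for (i in ord) {
    if (!alive[i]) next
    for (j in seq_len(nrow(sp))) {
      if (i == j || !alive[j]) next
      if (sp$contig[i] != sp$contig[j] || sp$strand[i] == sp$strand[j]) next
      if (spanLen[j] >= spanLen[i]) next           # only strictly smaller genes
      if (sp$start[j] > sp$end[i] || sp$start[i] > sp$end[j]) next
      seg <- genes@segments[genes@segments$gene_id == sp$gene_id[j], , drop = FALSE]
      inside <- sum(pmax(0L, pmin(seg$end, sp$end[i]) - pmax(seg$start, sp$start[i]) + 1L))
      outside <- sum(seg$end - seg$start + 1L) - inside
      if (outside < cfg$nested_frac * sum(seg$end - seg$start + 1L))
        alive[j] <- FALSE
    }
  }
  .subsetGenes(genes, sp$gene_id[alive])
}

#' Force gene predictions in transcripts without any
#'
#' Transcripts whose genomic extent overlaps no final gene's CDS are re-run
#' through the stage-1 model with the transition into the non-coding
#' transcript state set to zero, forcing at least one gene per parse.  The
#' result is reported separately and never enters the main annotation.
#'
#' @param stage1Model a [Stage1Model-class].
#' @param splicedAll output of [spliceAll()].
#' @param finalGenes the main annotation [GeneSet-class].
#' @return a [GeneSet-class] with provenance "dubious".
#' @export
predictDubious <- function(stage1Model, splicedAll, finalGenes) {
  sp <- .geneSpans(finalGenes)
  genes <- list(); segs <- list()
  for (id in names(splicedAll)) {
    sps <- splicedAll[[id]]
    ext <- range(unlist(lapply(sps, function(s) range(s@coordMap))))
    contig <- sps[[1]]@contig
    covered <- any(sp$contig == contig & sp$start <= ext[2] & ext[1] <= sp$end)
    if (covered) next
    dec <- lapply(sps, function(spl) .decodeTranscript(stage1Model, spl,
                                                       forbidNoncoding = TRUE))
    okv <- vapply(dec, function(d) !is.null(d) && isTRUE(d$ok), TRUE)
    if (!any(okv)) next                    # degenerate: no admissible forced parse
    lp <- vapply(dec, function(d) if (!is.null(d) && isTRUE(d$ok)) d$logprob else -Inf, 0)
    pick <- which.max(lp)
    g <- .genesFromParse(stage1Model, sps[[pick]], dec[[pick]], "dubious")
    if (!is.null(g)) { genes <- c(genes, list(g$genes)); segs <- c(segs, list(g$segs)) }
  }
  if (!length(genes)) return(emptyGeneSet())
  .renameGenes(newGeneSet(do.call(rbind, genes), do.call(rbind, segs)),
               prefix = "DUB")
}

#' Report transcripts suspected to be merged (fused) assemblies
#'
#' A transcript is listed when the coding sequences of two or more final genes
#' overlap its genomic extent; the report gives the constituent count and the
#' strand pattern in genomic order.
#'
#' @param finalGenes the main annotation [GeneSet-class].
#' @param txa [TranscriptAlignments-class].
#' @return data.frame(transcript_id, n_constituents, strand_pattern).
#' @export
reportFusions <- function(finalGenes, txa) {
  sp <- .geneSpans(finalGenes)
  rows <- list(); n <- 0L
  for (i in seq_len(nrow(txa@tx))) {
    id <- txa@tx$transcript_id[i]
    ex <- txa@exons[txa@exons$transcript_id == id, , drop = FALSE]
    lo <- min(ex$start); hi <- max(ex$end)
    hit <- sp[sp$contig == ex$contig[1] & sp$start <= hi & lo <= sp$end, , drop = FALSE]
    if (nrow(hit) < 2L) next
    hit <- hit[order(hit$start), , drop = FALSE]
    n <- n + 1L
    rows[[n]] <- data.frame(transcript_id = id, n_constituents = nrow(hit),
                            strand_pattern = paste(hit$strand, collapse = ""),
                            stringsAsFactors = FALSE)
  }
  if (!n) return(data.frame(transcript_id = character(),
                            n_constituents = integer(),
                            strand_pattern = character()))
  do.call(rbind, rows)
}

#' Write a fusion report as TSV
#' @param fusions output of [reportFusions()].
#' @param path output file.
#' @export
writeFusionReport <- function(fusions, path) {
  write.table(fusions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
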