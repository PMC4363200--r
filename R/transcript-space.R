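## Virtual splicing, coordinate lifting and open-reading-frame scanning.

#' Virtually splice a transcript alignment
#'
#' Concatenates the exon subsequences in genomic order (introns removed).  For
#' the reverse orientation the sequence is reverse-complemented and the
#' coordinate map decreases.  For a transcript of unknown strand and no
#' `assumeStrand`, both orientations are returned for downstream competition.
#'
#' @param genome a DNAStringSet (see [readGenome()]).
#' @param txa a [TranscriptAlignments-class].
#' @param transcriptId the transcript to splice.
#' @param assumeStrand optional "+" or "-" overriding the recorded strand.
#' @return list of one or two [SplicedTranscript-class] objects.
#' @export
spliceTranscript <- function(genome, txa, transcriptId, assumeStrand = NULL) {
  ex <- txa@exons[txa@exons$transcript_id == transcriptId, , drop = FALSE]
  if (!nrow(ex)) stop("unknown transcript: ", transcriptId)
  tx <- txa@tx[txa@tx$transcript_id == transcriptId, , drop = FALSE]
  contig <- tx$contig
  if (!contig %in% names(genome)) stop("contig ", contig, " not in genome")
  clen <- Biostrings::width(genome[contig])
  if (any(ex$start < 1L) || any(ex$end > clen))
    stop("exon outside contig bounds for transcript ", transcriptId)

  strands <- if (!is.null(assumeStrand)) assumeStrand
             else if (tx$strand == "*") c("+", "-") else tx$strand

  contigSeq <- as.character(genome[[contig]])
  pieces <- substring(contigSeq, ex$start, ex$end)
  fwd <- encodeDNA(paste(pieces, collapse = ""))
  map <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i]),
                use.names = FALSE)
  introns <- if (nrow(ex) > 1L)
    data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
  else data.frame(start = integer(), end = integer())

  lapply(strands, function(s) {
    if (s == "+")
      new("SplicedTranscript", transcriptId = transcriptId, contig = contig,
          strandUsed = "+", codes = fwd, coordMap = as.integer(map),
          evidencedIntrons = introns)
    else
      new("SplicedTranscript", transcriptId = transcriptId, contig = contig,
          strandUsed = "-", codes = revcompCodes(fwd),
          coordMap = as.integer(rev(map)), evidencedIntrons = introns)
  })
}

#' Lift a transcript-space interval back to genomic segments
#'
#' Returns the minimal set of maximal genomic segments covering the interval,
#' split exactly at the evidenced introns, in ascending genomic order.
#'
#' @param st a [SplicedTranscript-class].
#' @param start,end transcript-space interval (1-based inclusive).
#' @return data.frame(start, end) of genomic segments.
#' @export
liftToGenome <- function(st, start, end) {
  L <- length(st@codes)
  if (start < 1L || end > L || start > end)
    stop("interval [", start, ",", end, "] outside transcript of length ", L)
  g <- st@coordMap[start:end]
  if (st@strandUsed == "-") g <- rev(g)
  brk <- c(0L, which(diff(g) != 1L), length(g))
  out <- data.frame(start = g[brk[-length(brk)] + 1L], end = g[brk[-1]])
  out[order(out$start), , drop = FALSE]
}

#' Find open reading frames
#'
#' An ORF runs from an ATG to the first in-frame stop codon (TAA/TAG/TGA),
#' inclusive.  ORFs reaching the 3' end without a stop are reported with
#' `has_stop = FALSE` (needed to detect transcripts incomplete at the 3' end).
#'
#' @param x DNA string or integer codes.
#' @return data.frame(start, end, has_start, has_stop), one row per ATG.
#' @export
findOrfs <- function(x) {
  codes <- if (is.character(x)) encodeDNA(x) else as.integer(x)
  L <- length(codes)
  empty <- data.frame(start = integer(), end = integer(),
                      has_start = logical(), has_stop = logical())
  if (L < 3L) return(empty)
  i <- seq_len(L - 2L)
  isATG <- codes[i] == 1L & codes[i + 1L] == 4L & codes[i + 2L] == 3L
  isStop <- stopCodonStarts(codes)[i]
  out <- list(); n <- 0L
  for (fr in 0:2) {
    if (fr + 1L > L - 2L) next
    pos <- seq(fr + 1L, L - 2L, by = 3L)
    if (!length(pos)) next
    atg <- pos[isATG[pos]]
    stp <- pos[isStop[pos]]
    if (!length(atg)) next
    nxt <- findInterval(atg - 1L, stp) + 1L    # first stop at or after atg
    for (j in seq_along(atg)) {
      n <- n + 1L
      if (nxt[j] <= length(stp)) {
        out[[n]] <- data.frame(start = atg[j], end = stp[nxt[j]] + 2L,
                               has_start = TRUE, has_stop = TRUE)
      } else {
        lastFull <- atg[j] + ((L - atg[j] + 1L) %/% 3L) * 3L - 1L
        out[[n]] <- data.frame(start = atg[j], end = lastFull,
                               has_start = TRUE, has_stop = FALSE)
      }
    }
  }
  if (!n) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Longest methionine-initiated ORF
#'
#' @param x DNA string or integer codes.
#' @param requireStop only consider ORFs terminated by an in-frame stop.
#' @return one-row data.frame as in [findOrfs()], or NULL when none exists.
#'   Length ties are broken by the smallest start position.
#' @export
longestMetOrf <- function(x, requireStop = TRUE) {
  orfs <- findOrfs(x)
  if (requireStop) orfs <- orfs[orfs$has_stop, , drop = FALSE]
  if (!nrow(orfs)) return(NULL)
  len <- orfs$end - orfs$start + 1L
  best <- which(len == max(len))
  orfs[best[which.min(orfs$start[best])], , drop = FALSE]
}

#' Extract the spliced CDS sequence of a gene model
#' @param genome DNAStringSet.
#' @param genes a [GeneSet-class].
#' @param geneId gene to extract.
#' @return character string of the CDS in translation orientation.
#' @export
geneCdsSeq <- function(genome, genes, geneId) {
  g <- genes@genes[genes@genes$gene_id == geneId, , drop = FALSE]
  seg <- genes@segments[genes@segments$gene_id == geneId, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  contigSeq <- as.character(genome[[g$contig]])
  s <- paste(substring(contigSeq, seg$start, seg$end), collapse = "")
  if (g$strand == "-") s <- revcompDNA(s)
  s
}

## GFF3 phases for CDS segments listed in ascending genomic order.
.segmentPhases <- function(start, end, strand) {
  lens <- end - start + 1L
  ord <- if (strand == "+") seq_along(lens) else rev(seq_along(lens))
  cum <- c(0L, cumsum(lens[ord]))[seq_along(lens)]
  ph <- (3L - (cum %% 3L)) %% 3L
  out <- integer(length(lens))
  out[ord] <- ph
  out
}
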