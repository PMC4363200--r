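#' @import methods
#' @importFrom stats qchisq rbinom rgamma rlnorm runif setNames quantile
#' @importFrom utils head tail write.table read.table
NULL

## ---------------------------------------------------------------------------
## Emission models
## ---------------------------------------------------------------------------

#' Markov chain emission model
#'
#' A k-order Markov chain over DNA, optionally three-periodic (one conditional
#' table per codon position, as used for coding sequence).  Backoff tables of
#' orders 0..k-1 are estimated alongside the full-order table so that the
#' first k positions of a segment can be scored on segment-local context.
#'
#' @slot order non-negative integer, the context length k.
#' @slot periodic logical; TRUE for a three-periodic (codon-position) chain.
#' @slot tables list over phase (length 1 or 3) of lists over orders 0..k of
#'   probability matrices (4^m rows of contexts, 4 columns of next base).
#' @slot pseudocount positive pseudocount added per table cell at training.
#' @slot nFloorLog log-probability assigned to positions whose base or context
#'   contains an ambiguity character.
#' @exportClass MarkovChainModel
setClass("MarkovChainModel", representation(
  order = "integer", periodic = "logical", tables = "list",
  pseudocount = "numeric", nFloorLog = "numeric"
))

setValidity("MarkovChainModel", function(object) {
  nph <- if (object@periodic) 3L else 1L
  if (length(object@tables) != nph) return("tables must have one entry per phase")
  for (ph in seq_len(nph)) {
    if (length(object@tables[[ph]]) != object@order + 1L)
      return("need one table per order 0..k")
    for (m in seq_len(object@order + 1L)) {
      tab <- object@tables[[ph]][[m]]
      if (!is.matrix(tab) || ncol(tab) != 4L || nrow(tab) != 4^(m - 1L))
        return("table dimensions inconsistent with order")
      if (any(abs(rowSums(tab) - 1) > 1e-9)) return("conditional rows must sum to 1")
      if (object@pseudocount > 0 && any(tab <= 0)) return("probabilities must be > 0")
    }
  }
  TRUE
})

#' Weighted array matrix (position-specific k-order model)
#'
#' @slot order context order within the window.
#' @slot windowLength window width in nucleotides.
#' @slot positionTables list (length windowLength) of lists over orders
#'   0..min(order, pos-1) of conditional probability matrices.
#' @slot pseudocount positive pseudocount per cell.
#' @slot nFloorLog ambiguity-character floor.
#' @exportClass WeightedArrayMatrix
setClass("WeightedArrayMatrix", representation(
  order = "integer", windowLength = "integer", positionTables = "list",
  pseudocount = "numeric", nFloorLog = "numeric"
))

setValidity("WeightedArrayMatrix", function(object) {
  if (length(object@positionTables) != object@windowLength)
    return("one table set per window position required")
  for (p in seq_len(object@windowLength)) {
    tabs <- object@positionTables[[p]]
    for (tab in tabs) {
      if (any(abs(rowSums(tab) - 1) > 1e-9)) return("conditional rows must sum to 1")
    }
  }
  TRUE
})

#' Literal motif emission (e.g. the stop codon state)
#'
#' @slot motifs character vector of admissible words (equal length).
#' @slot logp named log-probabilities, one per motif, summing to 1 on the
#'   probability scale.
#' @exportClass MotifEmission
setClass("MotifEmission", representation(motifs = "character", logp = "numeric"))

setValidity("MotifEmission", function(object) {
  if (length(object@motifs) != length(object@logp)) return("one log-probability per motif")
  if (length(unique(nchar(object@motifs))) != 1L) return("motifs must share one length")
  if (abs(sum(exp(object@logp)) - 1) > 1e-6) return("motif probabilities must sum to 1")
  TRUE
})

## ---------------------------------------------------------------------------
## Duration models
## ---------------------------------------------------------------------------

#' State duration model
#'
#' Either a fixed length, or a smoothed empirical length distribution on a
#' regular grid (step 1, or step 3 for coding states) with a geometric tail
#' above the support maximum.
#'
#' @slot kind "fixed" or "empirical".
#' @slot fixedLength the single admissible duration (kind = "fixed").
#' @slot support integer c(min, max) of the empirical grid.
#' @slot step grid step (3 for codon-quantised durations).
#' @slot logp log-probabilities over the grid seq(min, max, by = step).
#' @slot tailLogMass log of the probability mass above the support maximum.
#' @slot tailRate per-step geometric success probability of the tail.
#' @slot tailCap steps of geometric tail materialised for decoding: NA for the
#'   default heuristic (one support width, at least 300 nt), -1 for unbounded
#'   (up to the decoded sequence length).
#' @exportClass DurationModel
setClass("DurationModel", representation(
  kind = "character", fixedLength = "integer", support = "integer",
  step = "integer", logp = "numeric", tailLogMass = "numeric",
  tailRate = "numeric", tailCap = "integer"
))

setValidity("DurationModel", function(object) {
  if (!object@kind %in% c("fixed", "empirical")) return("kind must be fixed or empirical")
  if (object@kind == "empirical") {
    grid <- seq(object@support[1], object@support[2], by = object@step)
    if (length(object@logp) != length(grid)) return("logp length must match support grid")
    if (any(!is.finite(object@logp))) return("log-probabilities must be finite on support")
    tot <- sum(exp(object@logp)) + exp(object@tailLogMass)
    if (tot > 1 + 1e-6) return("distribution mass exceeds 1")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Generalised HMM specification
## ---------------------------------------------------------------------------

#' Generalised hidden Markov model specification
#'
#' States emit variable-length segments; transitions act between segments.
#' For every state, transition probabilities out of it plus its end
#' probability sum to 1.
#'
#' @slot states character vector of state names.
#' @slot transitions square probability matrix (from = row, to = column).
#' @slot begin initial state probabilities.
#' @slot end per-state end probabilities.
#' @slot emissions named list of emission models (MarkovChainModel,
#'   WeightedArrayMatrix or MotifEmission), one per state.
#' @slot durations named list of DurationModel, one per state.
#' @slot entryPhase named integer; for three-periodic emission states, the
#'   codon phase at which a segment of that state begins.
#' @exportClass GhmmSpec
setClass("GhmmSpec", representation(
  states = "character", transitions = "matrix", begin = "numeric",
  end = "numeric", emissions = "list", durations = "list",
  entryPhase = "integer"
))

setValidity("GhmmSpec", function(object) {
  n <- length(object@states)
  if (any(duplicated(object@states))) return("state names must be unique")
  if (!all(dim(object@transitions) == c(n, n))) return("transition matrix must be n x n")
  if (length(object@begin) != n || length(object@end) != n)
    return("begin/end must have one entry per state")
  tot <- rowSums(object@transitions) + object@end
  if (any(abs(tot - 1) > 1e-9)) return("outgoing transition + end mass must sum to 1")
  if (abs(sum(object@begin) - 1) > 1e-9) return("begin probabilities must sum to 1")
  if (!setequal(names(object@emissions), object@states)) return("one emission model per state")
  if (!setequal(names(object@durations), object@states)) return("one duration model per state")
  TRUE
})

setMethod("show", "GhmmSpec", function(object) {
  cat("GhmmSpec with", length(object@states), "states:",
      paste(object@states, collapse = ", "), "\n")
  emcls <- vapply(object@emissions[object@states], function(e) class(e)[1], "")
  dur <- vapply(object@durations[object@states], function(d)
    if (d@kind == "fixed") paste0("fixed(", d@fixedLength, ")")
    else paste0("empirical[", d@support[1], ",", d@support[2], "]"), "")
  for (i in seq_along(object@states))
    cat(sprintf("  %-22s %-20s %s\n", object@states[i], emcls[i], dur[i]))
  invisible(object)
})

## ---------------------------------------------------------------------------
## Alignments and gene models
## ---------------------------------------------------------------------------

#' Assembled transcript alignments
#'
#' One row per exon block of each assembled transcript aligned to the genome.
#' Strand is "+", "-" or "*" (unknown, as from unstranded RNA-seq).
#'
#' @slot exons data.frame with columns transcript_id, contig, start, end
#'   (1-based inclusive, sorted ascending within transcript).
#' @slot tx data.frame with columns transcript_id, contig, strand, line
#'   (first source line, for error messages).
#' @exportClass TranscriptAlignments
setClass("TranscriptAlignments", representation(exons = "data.frame", tx = "data.frame"))

setValidity("TranscriptAlignments", function(object) {
  ex <- object@exons; tx <- object@tx
  need <- c("transcript_id", "contig", "start", "end")
  if (!all(need %in% names(ex))) return("exons must have transcript_id/contig/start/end")
  if (!all(c("transcript_id", "contig", "strand") %in% names(tx)))
    return("tx must have transcript_id/contig/strand")
  if (any(duplicated(tx$transcript_id))) return("transcript ids must be unique")
  if (any(ex$start > ex$end)) return("exon start must be <= end")
  if (!all(tx$strand %in% c("+", "-", "*"))) return("strand must be +, - or *")
  for (id in tx$transcript_id) {
    s <- ex$start[ex$transcript_id == id]
    e <- ex$end[ex$transcript_id == id]
    if (is.unsorted(s)) return(paste0("exons of ", id, " not in ascending order"))
    if (length(s) > 1L && any(s[-1] <= e[-length(e)]))
      return(paste0("overlapping exons in transcript ", id))
  }
  TRUE
})

setMethod("show", "TranscriptAlignments", function(object) {
  cat("TranscriptAlignments:", nrow(object@tx), "transcripts,",
      nrow(object@exons), "exon blocks on",
      length(unique(object@tx$contig)), "contig(s)\n")
  st <- table(factor(object@tx$strand, levels = c("+", "-", "*")))
  cat("  strand: +", st[["+"]], " -", st[["-"]], " unknown", st[["*"]], "\n")
  invisible(object)
})

#' A virtually spliced transcript
#'
#' Exon blocks concatenated (introns removed), reverse-complemented when the
#' orientation used is reverse, together with an invertible coordinate map
#' back to the genome.
#'
#' @slot transcriptId source transcript.
#' @slot contig contig id.
#' @slot strandUsed "+" or "-": the orientation this spliced sequence reads in.
#' @slot codes integer-encoded spliced sequence.
#' @slot coordMap integer vector: genomic position of each transcript position
#'   (strictly increasing for "+", strictly decreasing for "-").
#' @slot evidencedIntrons data.frame(start, end) genomic intron coordinates
#'   implied by the exon gaps (ascending).
#' @exportClass SplicedTranscript
setClass("SplicedTranscript", representation(
  transcriptId = "character", contig = "character", strandUsed = "character",
  codes = "integer", coordMap = "integer", evidencedIntrons = "data.frame"
))

setValidity("SplicedTranscript", function(object) {
  if (length(object@codes) != length(object@coordMap))
    return("coordMap must map every transcript position")
  d <- diff(object@coordMap)
  if (object@strandUsed == "+" && any(d <= 0)) return("coordMap must increase on +")
  if (object@strandUsed == "-" && any(d >= 0)) return("coordMap must decrease on -")
  TRUE
})

#' A set of predicted (or reference) gene models
#'
#' @slot genes data.frame with one row per gene: gene_id, transcript_id (NA
#'   when unsupported), contig, strand, provenance ("stage1", "stage2",
#'   "dubious" or "reference"), complete5, complete3, score, alt (logical;
#'   TRUE for candidates from alternative-splice windows).
#' @slot segments data.frame with one row per CDS segment: gene_id, start,
#'   end, phase (GFF3 phase), in ascending genomic order within gene.
#' @exportClass GeneSet
setClass("GeneSet", representation(genes = "data.frame", segments = "data.frame"))

setValidity("GeneSet", function(object) {
  g <- object@genes; s <- object@segments
  needg <- c("gene_id", "contig", "strand", "provenance")
  if (!all(needg %in% names(g))) return("genes must have gene_id/contig/strand/provenance")
  if (!all(c("gene_id", "start", "end", "phase") %in% names(s)))
    return("segments must have gene_id/start/end/phase")
  if (any(duplicated(g$gene_id))) return("gene ids must be unique")
  if (!all(g$strand %in% c("+", "-"))) return("gene strand must be + or -")
  if (!all(s$gene_id %in% g$gene_id)) return("orphan segments")
  if (any(s$start > s$end)) return("segment start must be <= end")
  TRUE
})

setMethod("show", "GeneSet", function(object) {
  g <- object@genes
  cat("GeneSet:", nrow(g), "genes (",
      paste(names(table(g$provenance)), table(g$provenance), collapse = ", "),
      ")\n")
  invisible(object)
})

#' Burset-Guigo evaluation report
#'
#' @slot mode "full" or "bounded".
#' @slot table data.frame with columns level, tp, reference_total,
#'   predicted_total, sensitivity, specificity (percentages).
#' @exportClass EvaluationReport
setClass("EvaluationReport", representation(mode = "character", table = "data.frame"))

setMethod("show", "EvaluationReport", function(object) {
  cat("Burset-Guigo evaluation (", object@mode, " mode)\n", sep = "")
  tb <- object@table
  cat(sprintf("  %-10s %6s %6s %6s %7s %7s\n", "level", "TP", "ref", "pred", "Sn", "Sp"))
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-10s %6d %6d %6d %7.1f %7.1f\n", tb$level[i], tb$tp[i],
                tb$reference_total[i], tb$predicted_total[i],
                tb$sensitivity[i], tb$specificity[i]))
  invisible(object)
})

## ---------------------------------------------------------------------------
## Stage models
## ---------------------------------------------------------------------------

#' Transcript-space (stage 1) gene model
#'
#' @slot spec the underlying GhmmSpec.
#' @slot config the run configuration used at training.
#' @slot trainingSizes integer vector: coding training examples per
#'   self-training round.
#' @exportClass Stage1Model
setClass("Stage1Model", representation(
  spec = "GhmmSpec", config = "list", trainingSizes = "integer"
))

setMethod("show", "Stage1Model", function(object) {
  cat("Stage1Model (transcript-space GHMM)\n")
  cat("  training set sizes by round:",
      paste(object@trainingSizes, collapse = " -> "), "\n")
  show(object@spec)
  invisible(object)
})

#' Genome-space (stage 2) gene model
#'
#' @slot spec the phase-expanded GhmmSpec with the intron sub-model.
#' @slot donorLength,acceptorLength fitted splice-boundary window lengths
#'   (total, including the 2 exonic nucleotides).
#' @slot maxIntron maximum intron length admitted by the decoder.
#' @slot minIntron minimum intron length.
#' @slot config the run configuration used at training.
#' @exportClass Stage2Model
setClass("Stage2Model", representation(
  spec = "GhmmSpec", donorLength = "integer", acceptorLength = "integer",
  maxIntron = "integer", minIntron = "integer", config = "list"
))

setMethod("show", "Stage2Model", function(object) {
  cat("Stage2Model (genome-space GHMM)\n")
  cat("  donor/acceptor window:", object@donorLength, "/",
      object@acceptorLength, "nt (incl. 2 exonic)\n")
  cat("  intron length range: [", object@minIntron, ",", object@maxIntron, "]\n")
  cat(" ", length(object@spec@states), "states\n")
  invisible(object)
})

#' Synthetic genome with known truth
#'
#' @slot genome DNAStringSet.
#' @slot truth GeneSet of the generating gene models.
#' @slot transcripts TranscriptAlignments (the corrupted "assembly").
#' @slot labels data.frame of per-transcript corruption labels.
#' @slot params the SynthParams list used.
#' @slot generator list of the generating emission tables (coding chain,
#'   background chain, splice/Kozak consensi) for recovery tests.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth", representation(
  genome = "ANY", truth = "GeneSet", transcripts = "TranscriptAlignments",
  labels = "data.frame", params = "list", generator = "list"
))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@truth@genes), "genes on",
      length(object@genome), "contig(s);",
      nrow(object@transcripts@tx), "transcript alignments\n")
  invisible(object)
})
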