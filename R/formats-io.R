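## FASTA / GTF / GFF3 input and GFF3 output.

#' Read a genome FASTA file
#'
#' Sequences are uppercased; contig ids are the header text up to the first
#' whitespace.  Characters outside A, C, G, T, N are rejected.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] of contigs.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  gen <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!length(gen)) stop("no sequences in ", path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  dup <- names(gen)[duplicated(names(gen))]
  if (length(dup)) stop("duplicate contig id(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  if (any(Biostrings::width(gen) == 0L)) stop("empty sequence in ", path)
  gen <- Biostrings::DNAStringSet(toupper(as.character(gen)))
  bad <- Biostrings::letterFrequency(gen, letters = "ACGTN")
  widths <- Biostrings::width(gen)
  off <- which(rowSums(bad) != widths)
  if (length(off))
    stop("contig ", names(gen)[off[1]],
         " contains characters outside {A,C,G,T,N}")
  gen
}

#' Construct transcript alignments from exon tables
#'
#' Exon gaps shorter than `minIntron` nucleotides are treated as alignment
#' noise and merged into a single exon.
#'
#' @param exons data.frame(transcript_id, contig, start, end).
#' @param strand named character vector (+ / - / *) per transcript.
#' @param line optional named integer of first source lines.
#' @param minIntron minimum accepted evidenced intron length.
#' @return a [TranscriptAlignments-class].
#' @export
transcriptAlignments <- function(exons, strand, line = NULL, minIntron = 4L) {
  ids <- unique(exons$transcript_id)
  outx <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    e <- exons[exons$transcript_id == ids[i], , drop = FALSE]
    e <- e[order(e$start, e$end), , drop = FALSE]
    m <- mergeIntervals(e$start, e$end)
    ## merge across sub-minimum gaps
    if (nrow(m) > 1L) {
      gap <- m$start[-1] - m$end[-nrow(m)] - 1L
      grp <- cumsum(c(1L, as.integer(gap >= minIntron)))
      m <- data.frame(start = tapply(m$start, grp, min),
                      end = tapply(m$end, grp, max))
    }
    outx[[i]] <- data.frame(transcript_id = ids[i], contig = e$contig[1],
                            start = as.integer(m$start), end = as.integer(m$end),
                            stringsAsFactors = FALSE)
  }
  ex <- do.call(rbind, outx)
  rownames(ex) <- NULL
  tx <- data.frame(transcript_id = ids,
                   contig = vapply(ids, function(id)
                     exons$contig[exons$transcript_id == id][1], ""),
                   strand = unname(strand[ids]),
                   line = if (is.null(line)) NA_integer_ else unname(line[ids]),
                   stringsAsFactors = FALSE)
  new("TranscriptAlignments", exons = ex, tx = tx)
}

#' Read assembled transcript alignments from GTF or GFF3
#'
#' Only `exon` features are used; the grouping attribute is `transcript_id`
#' (GTF) or `Parent` (GFF3).  Strand "." is kept as unknown ("*"), as arises
#' from unstranded RNA-seq assemblies.  The dialect is auto-detected from the
#' attribute syntax unless forced.
#'
#' @param path GTF/GFF3 file.
#' @param dialect "auto", "gtf" or "gff3".
#' @param minIntron exon gaps shorter than this are merged (alignment noise).
#' @return a [TranscriptAlignments-class].
#' @export
readTranscripts <- function(path, dialect = c("auto", "gtf", "gff3"),
                            minIntron = 4L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("transcript file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no feature lines in ", path)

  recs <- list(); n <- 0L
  for (ln in keep) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("format error at line ", ln, " of ", path, ": expected 9 tab-separated columns")
    if (tolower(f[3]) != "exon") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("format error at line ", ln, " of ", path, ": non-numeric coordinates")
    if (start > end)
      stop("format error at line ", ln, " of ", path, ": exon start > end")
    if (!f[7] %in% c("+", "-", "."))
      stop("format error at line ", ln, " of ", path, ": bad strand '", f[7], "'")
    attr <- f[9]
    d <- dialect
    if (d == "auto")
      d <- if (grepl("(^|;)\\s*[A-Za-z_]+=", attr)) "gff3" else "gtf"
    id <- if (d == "gtf") {
      m <- regmatches(attr, regexec('transcript_id\\s+"([^"]+)"', attr))[[1]]
      if (length(m) < 2L)
        stop("format error at line ", ln, " of ", path, ": missing transcript_id")
      m[2]
    } else {
      m <- regmatches(attr, regexec("(?:^|;)\\s*Parent=([^;]+)", attr))[[1]]
      if (length(m) < 2L)
        stop("format error at line ", ln, " of ", path, ": missing Parent attribute")
      strsplit(m[2], ",", fixed = TRUE)[[1]][1]
    }
    n <- n + 1L
    recs[[n]] <- data.frame(transcript_id = id, contig = f[1], start = start,
                            end = end, strand = f[7], line = ln,
                            stringsAsFactors = FALSE)
  }
  if (!n) stop("no exon features in ", path)
  ex <- do.call(rbind, recs)

  strand <- character(); firstline <- integer()
  for (id in unique(ex$transcript_id)) {
    sub <- ex[ex$transcript_id == id, , drop = FALSE]
    if (length(unique(sub$contig)) > 1L)
      stop("consistency error: transcript ", id, " has exons on multiple contigs (",
           paste(unique(sub$contig), collapse = ", "), ")")
    st <- unique(sub$strand)
    if (length(st) > 1L)
      stop("consistency error: transcript ", id, " has conflicting strands")
    strand[id] <- if (st == ".") "*" else st
    firstline[id] <- min(sub$line)
  }
  transcriptAlignments(ex[c("transcript_id", "contig", "start", "end")],
                       strand, firstline, minIntron = minIntron)
}

.gff3Attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(v) is.null(v) || is.na(v), TRUE)]
  paste(paste0(names(kv), "=", unlist(kv)), collapse = ";")
}

#' Write gene models as GFF3
#'
#' One `gene`, one `mRNA` and ordered `CDS` features per gene model, with
#' provenance and completeness flags as attributes.  Coordinates are 1-based
#' inclusive; the phase column follows the GFF3 convention.
#'
#' @param genes a [GeneSet-class].
#' @param path output file.
#' @export
writeGFF3 <- function(genes, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- genes@genes; s <- genes@segments
  if (!nrow(g)) return(invisible(path))
  o <- order(g$contig, vapply(g$gene_id, function(id)
    min(s$start[s$gene_id == id]), 0L))
  for (i in o) {
    id <- g$gene_id[i]
    seg <- s[s$gene_id == id, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    lo <- min(seg$start); hi <- max(seg$end)
    score <- if (!is.null(g$score) && is.finite(g$score[i]))
      sprintf("%.3f", g$score[i]) else "."
    gat <- .gff3Attr(ID = id,
                     provenance = g$provenance[i],
                     supporting_transcript =
                       if (!is.null(g$transcript_id)) g$transcript_id[i] else NA,
                     complete5prime = tolower(as.character(g$complete5[i])),
                     complete3prime = tolower(as.character(g$complete3[i])))
    writeLines(paste(g$contig[i], "SporeCall", "gene", lo, hi, ".",
                     g$strand[i], ".", gat, sep = "\t"), con)
    mid <- paste0(id, ".mRNA")
    writeLines(paste(g$contig[i], "SporeCall", "mRNA", lo, hi, score,
                     g$strand[i], ".", .gff3Attr(ID = mid, Parent = id), sep = "\t"), con)
    for (j in seq_len(nrow(seg)))
      writeLines(paste(g$contig[i], "SporeCall", "CDS", seg$start[j], seg$end[j],
                       ".", g$strand[i], seg$phase[j],
                       .gff3Attr(ID = paste0(id, ".CDS"), Parent = mid), sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reads `CDS` features grouped by their `Parent`; accepts both this package's
#' output and plain reference annotations (gene/mRNA/CDS).
#'
#' @param path GFF3 file.
#' @param provenance provenance label for genes lacking the attribute.
#' @return a [GeneSet-class].
#' @export
readGFF3Genes <- function(path, provenance = "reference") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  cds <- list(); nc <- 0L
  meta <- list()
  parentOf <- character()   # mRNA id -> gene id
  for (ln in keep) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) next
    attr <- f[9]
    getA <- function(key) {
      m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr))[[1]]
      if (length(m) < 2L) NA_character_ else m[2]
    }
    type <- tolower(f[3])
    if (type == "gene") {
      id <- getA("ID")
      if (!is.na(id))
        meta[[id]] <- list(provenance = getA("provenance"),
                           transcript_id = getA("supporting_transcript"),
                           complete5 = getA("complete5prime"),
                           complete3 = getA("complete3prime"))
    } else if (type == "mrna") {
      id <- getA("ID"); par <- getA("Parent")
      if (!is.na(id) && !is.na(par)) parentOf[id] <- par
    } else if (type == "cds") {
      par <- getA("Parent")
      if (is.na(par)) par <- getA("ID")
      if (is.na(par)) stop("CDS without Parent at line ", ln, " of ", path)
      nc <- nc + 1L
      cds[[nc]] <- data.frame(parent = strsplit(par, ",")[[1]][1], contig = f[1],
                              start = as.integer(f[4]), end = as.integer(f[5]),
                              strand = f[7],
                              phase = if (f[8] == ".") 0L else as.integer(f[8]),
                              stringsAsFactors = FALSE)
    }
  }
  if (!nc) return(emptyGeneSet())
  cdf <- do.call(rbind, cds)
  genes <- list(); segs <- list(); i <- 0L
  for (par in unique(cdf$parent)) {
    sub <- cdf[cdf$parent == par, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gid <- if (par %in% names(parentOf)) parentOf[[par]] else par
    md <- meta[[gid]]
    i <- i + 1L
    genes[[i]] <- data.frame(
      gene_id = gid,
      transcript_id = if (!is.null(md) && !is.na(md$transcript_id)) md$transcript_id else NA_character_,
      contig = sub$contig[1], strand = sub$strand[1],
      provenance = if (!is.null(md) && !is.na(md$provenance)) md$provenance else provenance,
      complete5 = if (!is.null(md) && !is.na(md$complete5)) md$complete5 == "true" else TRUE,
      complete3 = if (!is.null(md) && !is.na(md$complete3)) md$complete3 == "true" else TRUE,
      score = NA_real_, alt = FALSE, stringsAsFactors = FALSE)
    segs[[i]] <- data.frame(gene_id = gid, start = sub$start, end = sub$end,
                            phase = sub$phase, stringsAsFactors = FALSE)
  }
  newGeneSet(do.call(rbind, genes), do.call(rbind, segs))
}

#' @keywords internal
emptyGeneSet <- function() {
  new("GeneSet",
      genes = data.frame(gene_id = character(), transcript_id = character(),
                         contig = character(), strand = character(),
                         provenance = character(), complete5 = logical(),
                         complete3 = logical(), score = numeric(),
                         alt = logical(), stringsAsFactors = FALSE),
      segments = data.frame(gene_id = character(), start = integer(),
                            end = integer(), phase = integer(),
                            stringsAsFactors = FALSE))
}

#' Assemble a GeneSet from gene and segment tables
#' @param genes,segments data.frames as documented for [GeneSet-class].
#' @return a validated [GeneSet-class].
#' @export
newGeneSet <- function(genes, segments) {
  if (is.null(genes) || !nrow(genes)) return(emptyGeneSet())
  for (col in c("transcript_id")) if (is.null(genes[[col]])) genes[[col]] <- NA_character_
  if (is.null(genes$score)) genes$score <- NA_real_
  if (is.null(genes$alt)) genes$alt <- FALSE
  if (is.null(genes$complete5)) genes$complete5 <- TRUE
  if (is.null(genes$complete3)) genes$complete3 <- TRUE
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$phase <- as.integer(segments$phase)
  rownames(genes) <- NULL; rownames(segments) <- NULL
  new("GeneSet", genes = genes, segments = segments)
}
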