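#' @importFrom Biostrings DNAString DNAStringSet readBStringSet
#'   writeXStringSet reverseComplement
#' @importFrom BiocGenerics start end width strand
#' @importFrom IRanges IRanges
NULL

# ---- constructors and accessors --------------------------------------------

#' Build a transcript model
#'
#' @param transcriptId,geneId,seqId identifiers; `seqId` names the genomic
#'   sequence the coordinates refer to.
#' @param strand `"+"` or `"-"`.
#' @param exons an [IRanges::IRanges] of exon intervals (1-based, closed,
#'   genomic), sorted by start and non-overlapping.
#' @param cdsStart,cdsEnd genomic positions of the leftmost and rightmost
#'   coding base.
#' @return a [TranscriptModel-class] object.
#' @examples
#' transcriptModel("tx1", "g1", "chr", "+",
#'                 IRanges::IRanges(c(1, 10), c(3, 12)), 1, 12)
#' @export
transcriptModel <- function(transcriptId, geneId = transcriptId, seqId,
                            strand, exons, cdsStart, cdsEnd) {
  new("TranscriptModel",
      transcriptId = as.character(transcriptId),
      geneId = as.character(geneId), seqId = as.character(seqId),
      strand = as.character(strand), exons = exons,
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
}

#' @rdname TranscriptModel-accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("cdsStart", function(x) standardGeneric("cdsStart"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("cdsEnd", function(x) standardGeneric("cdsEnd"))

#' Accessors for TranscriptModel and MatureTranscript
#'
#' @param x a [TranscriptModel-class] or [MatureTranscript-class].
#' @return the corresponding slot value.
#' @name TranscriptModel-accessors
#' @aliases transcriptId geneId exons cdsStart cdsEnd mrnaSequence
#'   junctions cdsStartMrna exonProvenance
NULL

#' @rdname TranscriptModel-accessors
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname TranscriptModel-accessors
setMethod("transcriptId", "MatureTranscript", function(x) x@transcriptId)
#' @rdname TranscriptModel-accessors
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
#' @rdname TranscriptModel-accessors
setMethod("exons", "TranscriptModel", function(x) x@exons)
#' @rdname TranscriptModel-accessors
setMethod("cdsStart", "TranscriptModel", function(x) x@cdsStart)
#' @rdname TranscriptModel-accessors
setMethod("cdsEnd", "TranscriptModel", function(x) x@cdsEnd)
#' @rdname TranscriptModel-accessors
setMethod("strand", "TranscriptModel", function(x, ...) x@strand)

#' @rdname TranscriptModel-accessors
#' @export
mrnaSequence <- function(x) x@sequence
#' @rdname TranscriptModel-accessors
#' @export
junctions <- function(x) x@junctions
#' @rdname TranscriptModel-accessors
#' @export
cdsStartMrna <- function(x) x@cdsStartMrna
#' @rdname TranscriptModel-accessors
#' @export
exonProvenance <- function(x) x@exonProvenance

# ---- FASTA ------------------------------------------------------------------

#' Read and normalize genomic sequences from FASTA
#'
#' Reads single- or multi-line FASTA records, uppercases, converts U to T,
#' and validates the alphabet against `{A,C,G,T,N}`. Malformed records are
#' reported by name.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet], one element per record.
#' @export
readGenome <- function(path) {
  raw <- readBStringSet(path)
  if (length(raw) == 0L)
    stop("no FASTA records found in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1L], " in '", path,
         "' has an empty header", call. = FALSE)
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i]))
      stop("FASTA record '", ids[i], "' is empty", call. = FALSE)
    checkDna(seqs[i], what = sprintf("FASTA record '%s'", ids[i]))
  }
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Reverse complement of a DNA character string
#'
#' Thin character-level wrapper around
#' [Biostrings::reverseComplement()]; `N` maps to `N`. ASO sequences are
#' the reverse complement of their sense-strand target window, so this is
#' the workhorse of candidate generation.
#'
#' @param seq a DNA string over `{A,C,G,T,N}`.
#' @return the reverse complement, as a character string.
#' @examples
#' revComp("AATTCC")  # "GGAATT"
#' @export
revComp <- function(seq) {
  checkDna(seq, what = "revComp input")
  as.character(reverseComplement(DNAString(seq)))
}

# ---- annotation I/O ---------------------------------------------------------

#' Read transcript models from GFF3 or GTF annotation
#'
#' Groups `exon` and `CDS` features by transcript and validates each model
#' (sorted, disjoint exons; CDS endpoints inside exons). Input coordinates
#' are 1-based inclusive per the GFF/GTF standard and are stored unchanged
#' in [IRanges::IRanges] form.
#'
#' @param path path to the annotation file.
#' @param dialect `"auto"` (by file extension), `"gff3"` or `"gtf"`.
#' @return a named list of [TranscriptModel-class] objects.
#' @export
readAnnotation <- function(path, dialect = c("auto", "gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf"
               else "gff3"
  gr <- rtracklayer::import(path, format = dialect)
  type <- tolower(as.character(gr$type))
  if (dialect == "gtf") {
    txId <- gr$transcript_id
    geneIdOf <- gr$gene_id
  } else {
    parent <- vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, character(1))
    txId <- sub("^transcript:", "", parent)
    # gene of each transcript comes from the transcript/mRNA feature rows
    isTx <- type %in% c("mrna", "transcript")
    txGene <- sub("^gene:", "", parent[isTx])
    names(txGene) <- sub("^transcript:", "", as.character(gr$ID[isTx]))
    geneIdOf <- txGene[txId]
  }
  keep <- type %in% c("exon", "cds")
  gr <- gr[keep]; type <- type[keep]
  txId <- txId[keep]; geneIdOf <- geneIdOf[keep]
  if (!length(gr))
    stop("no exon/CDS features found in '", path, "'", call. = FALSE)

  models <- list()
  for (tx in unique(txId)) {
    sel <- txId == tx
    ex <- gr[sel & type == "exon"]
    cds <- gr[sel & type == "cds"]
    if (!length(ex))
      stop("transcript '", tx, "' has CDS but no exon features",
           call. = FALSE)
    o <- order(start(ex))
    exR <- IRanges(start(ex)[o], end(ex)[o])
    gene <- geneIdOf[sel][1L]
    if (is.na(gene)) gene <- tx
    models[[tx]] <- transcriptModel(
      transcriptId = tx, geneId = gene,
      seqId = as.character(GenomicRanges::seqnames(ex))[1L],
      strand = as.character(strand(ex))[1L],
      exons = exR,
      cdsStart = if (length(cds)) min(start(cds)) else NA_integer_,
      cdsEnd = if (length(cds)) max(end(cds)) else NA_integer_)
  }
  models
}

#' Write transcript models as GFF3
#'
#' Inverse of [readAnnotation()] for the features this package uses
#' (gene/mRNA/exon/CDS rows, 1-based inclusive coordinates).
#'
#' @param models a list of [TranscriptModel-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    ex <- m@exons
    span <- c(min(start(ex)), max(end(ex)))
    row <- function(type, s, e, attrs)
      paste(m@seqId, "skipNMD", type, s, e, ".", m@strand, ".", attrs,
            sep = "\t")
    lines <- c(lines,
      row("gene", span[1], span[2], sprintf("ID=gene:%s", m@geneId)),
      row("mRNA", span[1], span[2],
          sprintf("ID=transcript:%s;Parent=gene:%s", m@transcriptId,
                  m@geneId)))
    for (i in seq_along(ex))
      lines <- c(lines, row("exon", start(ex)[i], end(ex)[i],
        sprintf("ID=exon:%s:%d;Parent=transcript:%s", m@transcriptId, i,
                m@transcriptId)))
    if (!is.na(m@cdsStart)) {
      cdsR <- IRanges::restrict(ex, m@cdsStart, m@cdsEnd)
      cdsR <- cdsR[width(cdsR) > 0L]
      for (i in seq_along(cdsR))
        lines <- c(lines, row("CDS", start(cdsR)[i], end(cdsR)[i],
          sprintf("ID=cds:%s;Parent=transcript:%s", m@transcriptId,
                  m@transcriptId)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- splicing and coordinate maps ------------------------------------------

# genome argument: a DNAStringSet (looked up by seqId), DNAString, or
# character string
resolveGenomeSeq <- function(genome, model) {
  if (is(genome, "DNAStringSet")) {
    if (!model@seqId %in% names(genome))
      stop("sequence '", model@seqId, "' not found in genome", call. = FALSE)
    return(as.character(genome[[model@seqId]]))
  }
  if (is(genome, "DNAString")) return(as.character(genome))
  if (is.character(genome) && length(genome) == 1L) return(genome)
  stop("genome must be a DNAStringSet, DNAString or character string",
       call. = FALSE)
}

#' Splice a transcript model to its mature mRNA
#'
#' Concatenates exon sequences in genomic order and, for minus-strand
#' transcripts, reverse-complements the result so downstream code sees a
#' single 5'-to-3' mRNA coordinate system. The junction chain (position of
#' the first nucleotide 3' of each exon-exon junction) and the CDS start
#' are recomputed in mRNA coordinates.
#'
#' @param genome a [Biostrings::DNAStringSet] (record looked up by the
#'   model's `seqId`), a `DNAString`, or a character string.
#' @param model a [TranscriptModel-class].
#' @param id transcript id to stamp on the product (default: the model's).
#' @return a [MatureTranscript-class].
#' @export
spliceTranscript <- function(genome, model, id = transcriptId(model)) {
  seq <- resolveGenomeSeq(genome, model)
  ex <- model@exons
  if (min(start(ex)) < 1L || max(end(ex)) > nchar(seq))
    stop("exon out of bounds for sequence '", model@seqId, "' (length ",
         nchar(seq), ")", call. = FALSE)
  pieces <- substring(seq, start(ex), end(ex))
  mrna <- paste(pieces, collapse = "")
  minus <- model@strand == "-"
  if (minus) mrna <- revComp(mrna)
  w <- if (minus) rev(width(ex)) else width(ex)
  junc <- if (length(w) > 1L) cumsum(w)[-length(w)] + 1L else integer()
  csGenomic <- if (minus) model@cdsEnd else model@cdsStart
  cs <- if (is.na(csGenomic)) NA_integer_
        else genomicToMrna(model, csGenomic)
  prov <- if (minus) rev(seq_along(ex)) else seq_along(ex)
  new("MatureTranscript", transcriptId = id,
      sequence = DNAString(mrna), junctions = as.integer(junc),
      cdsStartMrna = as.integer(cs), exonProvenance = as.integer(prov))
}

#' Map genomic positions to mRNA positions (and back)
#'
#' `genomicToMrna` maps 1-based genomic positions inside the transcript
#' span to 1-based mRNA positions; intronic positions map to `NA` and
#' positions outside the span are an error. On minus-strand transcripts
#' mRNA positions count from the 3' genomic end. `mrnaToGenomic` is the
#' exact inverse on exonic positions.
#'
#' @param model a [TranscriptModel-class].
#' @param gpos,mpos integer vector of positions.
#' @return an integer vector of mapped positions (`NA` for intronic input
#'   to `genomicToMrna`).
#' @export
genomicToMrna <- function(model, gpos) {
  ex <- model@exons
  lo <- min(start(ex)); hi <- max(end(ex))
  gpos <- as.integer(gpos)
  if (any(gpos < lo | gpos > hi))
    stop("position outside transcript span [", lo, ", ", hi, "]",
         call. = FALSE)
  minus <- model@strand == "-"
  n <- length(ex)
  ord <- if (minus) rev(seq_len(n)) else seq_len(n)
  cumBefore <- c(0L, cumsum(width(ex)[ord]))[seq_len(n)]
  out <- rep(NA_integer_, length(gpos))
  for (k in seq_len(n)) {
    i <- ord[k]
    hit <- gpos >= start(ex)[i] & gpos <= end(ex)[i]
    if (!any(hit)) next
    off <- if (minus) end(ex)[i] - gpos[hit] else gpos[hit] - start(ex)[i]
    out[hit] <- cumBefore[k] + off + 1L
  }
  out
}

#' @rdname genomicToMrna
#' @export
mrnaToGenomic <- function(model, mpos) {
  ex <- model@exons
  total <- sum(width(ex))
  mpos <- as.integer(mpos)
  if (any(mpos < 1L | mpos > total))
    stop("mRNA position outside [1, ", total, "]", call. = FALSE)
  minus <- model@strand == "-"
  n <- length(ex)
  ord <- if (minus) rev(seq_len(n)) else seq_len(n)
  bounds <- c(0L, cumsum(width(ex)[ord]))
  out <- integer(length(mpos))
  for (k in seq_len(n)) {
    i <- ord[k]
    hit <- mpos > bounds[k] & mpos <= bounds[k + 1L]
    if (!any(hit)) next
    off <- mpos[hit] - bounds[k] - 1L
    out[hit] <- if (minus) end(ex)[i] - off else start(ex)[i] + off
  }
  out
}
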