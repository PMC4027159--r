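#' @import methods
#' @importFrom IRanges IRanges
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importFrom BiocGenerics start end width strand
NULL

#' TranscriptModel: exon/CDS architecture of a protein-coding transcript
#'
#' Holds the exon layout and coding-region endpoints of one transcript on a
#' genomic (pre-mRNA) sequence. Exon intervals are stored as an
#' [IRanges::IRanges] in genomic coordinates (1-based, closed, the native
#' Bioconductor convention); file readers and writers convert to and from
#' the GFF3/GTF (1-based inclusive) and BED (0-based half-open) dialects at
#' the boundary.
#'
#' @slot transcriptId single transcript identifier.
#' @slot geneId gene the transcript belongs to.
#' @slot seqId identifier of the genomic sequence the coordinates refer to.
#' @slot strand `"+"` or `"-"`.
#' @slot exons `IRanges` of exon intervals, sorted by genomic start and
#'   pairwise disjoint.
#' @slot cdsStart,cdsEnd genomic positions (1-based) of the leftmost and
#'   rightmost coding base; both must fall inside exons. On the minus strand
#'   `cdsEnd` is the first transcribed coding base.
#'
#' @seealso [transcriptModel()], [spliceTranscript()], [readAnnotation()]
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId       = "character",
    seqId        = "character",
    strand       = "character",
    exons        = "IRanges",
    cdsStart     = "integer",
    cdsEnd       = "integer"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  for (slt in c("transcriptId", "geneId", "seqId", "strand"))
    if (length(slot(object, slt)) != 1L || is.na(slot(object, slt)))
      msg <- c(msg, sprintf("'%s' must be a single non-NA string", slt))
  if (length(object@strand) == 1L && !object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) < 1L) msg <- c(msg, "at least one exon is required")
  if (length(ex) > 1L) {
    if (is.unsorted(BiocGenerics::start(ex)))
      msg <- c(msg, "exons must be sorted by genomic start")
    if (any(BiocGenerics::start(ex)[-1L] <=
            BiocGenerics::end(ex)[-length(ex)]))
      msg <- c(msg, sprintf("overlapping exons in transcript '%s'",
                            object@transcriptId))
  }
  if (any(BiocGenerics::width(ex) < 1L))
    msg <- c(msg, "every exon must have length >= 1")
  inExon <- function(p) any(p >= BiocGenerics::start(ex) &
                            p <= BiocGenerics::end(ex))
  if (!is.na(object@cdsStart) && !inExon(object@cdsStart))
    msg <- c(msg, "cdsStart does not fall inside an exon")
  if (!is.na(object@cdsEnd) && !inExon(object@cdsEnd))
    msg <- c(msg, "cdsEnd does not fall inside an exon")
  if (!is.na(object@cdsStart) && !is.na(object@cdsEnd) &&
      object@cdsStart > object@cdsEnd)
    msg <- c(msg, "cdsStart must be <= cdsEnd (genomic order)")
  if (length(msg)) msg else TRUE
})

#' MatureTranscript: a spliced mRNA with its junction chain
#'
#' The spliced product of a [TranscriptModel] (or of a mis-splicing event),
#' fully normalized to transcript orientation: `sequence` reads 5' to 3'
#' regardless of genomic strand, and all positions are 1-based mRNA
#' coordinates.
#'
#' @slot transcriptId transcript identifier (suffixed with the event label
#'   for aberrant isoforms).
#' @slot sequence the mRNA as a [Biostrings::DNAString] (DNA alphabet).
#' @slot junctions integer vector of mRNA positions of the first nucleotide
#'   3' of each exon-exon junction, strictly increasing.
#' @slot cdsStartMrna mRNA position of the A of the start codon, or `NA`
#'   when the start codon was lost by the splicing event.
#' @slot exonProvenance integer indices of the source exons (in genomic
#'   order on the parent model) contributing sequence, listed in transcript
#'   order. Intron retention is recorded as the negative index of the
#'   retained intron spliced between its flanking exons.
#'
#' @seealso [spliceTranscript()], [scanOrf()], [classifyNmd()]
#' @export
setClass("MatureTranscript",
  representation(
    transcriptId   = "character",
    sequence       = "DNAString",
    junctions      = "integer",
    cdsStartMrna   = "integer",
    exonProvenance = "integer"
  )
)

setValidity("MatureTranscript", function(object) {
  msg <- character()
  n <- length(object@sequence)
  if (n < 1L) msg <- c(msg, "empty mRNA sequence")
  j <- object@junctions
  if (length(j) && (is.unsorted(j, strictly = TRUE) ||
                    any(j <= 1L) || any(j > n)))
    msg <- c(msg, "junctions must be strictly increasing positions in (1, length]")
  cs <- object@cdsStartMrna
  if (!is.na(cs) && (cs < 1L || cs > n - 2L))
    msg <- c(msg, "cdsStartMrna must leave room for at least one codon")
  if (length(msg)) msg else TRUE
})

# ---- mis-splicing events ----------------------------------------------------

#' Mis-splicing event classes
#'
#' Three event types describe how an antisense oligonucleotide can redirect
#' splicing of its target pre-mRNA: skipping of one or more contiguous
#' internal exons (`SkipEvent`), activation of a cryptic donor or acceptor
#' inside an exon so that only part of the exon is lost
#' (`CrypticSpliceEvent`), and retention of an intron (`RetentionEvent`).
#' All derive from the virtual class `SpliceEvent`.
#'
#' @slot exonIndices (`SkipEvent`) contiguous 1-based indices of the
#'   skipped exons, in genomic order; never the first or last exon.
#' @slot exonIndex (`CrypticSpliceEvent`) index of the affected exon.
#' @slot newBoundary (`CrypticSpliceEvent`) genomic position (1-based) of
#'   the last retained exonic base (`side = "donor"`) or the first retained
#'   base (`side = "acceptor"`); strictly inside the exon.
#' @slot side (`CrypticSpliceEvent`) `"donor"` (5'ss) or `"acceptor"`
#'   (3'ss), in genomic-plus orientation.
#' @slot intronIndex (`RetentionEvent`) index of the retained intron
#'   (between exon `i` and `i + 1`).
#'
#' @seealso [skipEvent()], [crypticSpliceEvent()], [retentionEvent()],
#'   [applyEvent()]
#' @name SpliceEvent-classes
#' @aliases SpliceEvent SkipEvent CrypticSpliceEvent RetentionEvent
NULL

#' @rdname SpliceEvent-classes
#' @export
setClass("SpliceEvent", representation("VIRTUAL"))

#' @rdname SpliceEvent-classes
#' @export
setClass("SkipEvent", contains = "SpliceEvent",
  representation(exonIndices = "integer"))

setValidity("SkipEvent", function(object) {
  ix <- object@exonIndices
  if (length(ix) < 1L) return("at least one exon index is required")
  if (any(diff(ix) != 1L)) return("skipped exon indices must be contiguous")
  if (any(ix < 2L)) return("the first exon cannot be skipped")
  TRUE
})

#' @rdname SpliceEvent-classes
#' @export
setClass("CrypticSpliceEvent", contains = "SpliceEvent",
  representation(exonIndex = "integer", newBoundary = "integer",
                 side = "character"))

setValidity("CrypticSpliceEvent", function(object) {
  if (!object@side %in% c("donor", "acceptor"))
    return("side must be 'donor' or 'acceptor'")
  TRUE
})

#' @rdname SpliceEvent-classes
#' @export
setClass("RetentionEvent", contains = "SpliceEvent",
  representation(intronIndex = "integer"))

#' IsoformRecord: the product of a mis-splicing event
#'
#' Pairs a [SpliceEvent-classes] (or `NULL` for the reference) with the
#' resulting [MatureTranscript] and bookkeeping needed for frameshift and
#' NMD classification.
#'
#' @slot event the generating event, or `NULL` for the reference isoform.
#' @slot mature the spliced isoform.
#' @slot removedCodingLength coding nucleotides removed relative to the
#'   reference mature transcript (>= 0; always 0 for intron retention).
#' @slot addedLength nucleotides added by intron retention (0 otherwise).
#' @slot startLost `TRUE` when the event removed the start codon; such
#'   records are excluded from frame and NMD classification.
#'
#' @seealso [applyEvent()], [frameDisruption()]
#' @export
setClass("IsoformRecord",
  representation(
    event               = "ANY",
    mature              = "MatureTranscript",
    removedCodingLength = "integer",
    addedLength         = "integer",
    startLost           = "logical"
  )
)

setValidity("IsoformRecord", function(object) {
  if (!is.na(object@removedCodingLength) && object@removedCodingLength < 0L)
    return("removedCodingLength must be >= 0")
  if (object@addedLength < 0L)
    return("addedLength must be >= 0")
  TRUE
})

#' NmdVerdict: outcome of the 55-nt last-junction rule
#'
#' Result of [classifyNmd()]: where translation terminates on the isoform,
#' whether that stop is premature, and whether the isoform is a predicted
#' substrate of nonsense-mediated decay under the last-junction distance
#' rule.
#'
#' @slot stopMrnaPos mRNA position (1-based) of the first nucleotide of the
#'   terminating stop codon.
#' @slot isPremature `TRUE` when the stop differs from the isoform-mapped
#'   reference stop.
#' @slot frameshift whether the generating event disrupted the reading
#'   frame (`NA` when unknown).
#' @slot distanceToLastJunction nucleotides from the first base of the stop
#'   codon to the last exon-exon junction (negative when the stop lies
#'   downstream of the last junction; `NA` for junction-less transcripts).
#' @slot nmdSubstrate `TRUE` when the stop is premature and lies strictly
#'   more than the configured threshold (default 55 nt) upstream of the
#'   last junction.
#'
#' @seealso [classifyNmd()], [nmdRuleConfig()]
#' @export
setClass("NmdVerdict",
  representation(
    stopMrnaPos            = "integer",
    isPremature            = "logical",
    frameshift             = "logical",
    distanceToLastJunction = "integer",
    nmdSubstrate           = "logical"
  )
)

setValidity("NmdVerdict", function(object) {
  if (isTRUE(object@nmdSubstrate) && !isTRUE(object@isPremature))
    return("an NMD substrate must carry a premature stop")
  TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "TranscriptModel", function(object) {
  ex <- object@exons
  cat(sprintf("TranscriptModel '%s' (gene '%s') on %s [%s]\n",
              object@transcriptId, object@geneId, object@seqId,
              object@strand))
  cat(sprintf("  %d exon(s), span %d..%d; CDS %s..%s\n",
              length(ex), min(BiocGenerics::start(ex)),
              max(BiocGenerics::end(ex)),
              object@cdsStart, object@cdsEnd))
})

setMethod("show", "MatureTranscript", function(object) {
  cat(sprintf("MatureTranscript '%s': %d nt, %d junction(s), CDS start %s\n",
              object@transcriptId, length(object@sequence),
              length(object@junctions), object@cdsStartMrna))
})

setMethod("show", "SkipEvent", function(object) {
  cat(sprintf("SkipEvent: exon(s) %s\n",
              paste(object@exonIndices, collapse = "+")))
})

setMethod("show", "CrypticSpliceEvent", function(object) {
  cat(sprintf("CrypticSpliceEvent: cryptic %s in exon %d at %d\n",
              object@side, object@exonIndex, object@newBoundary))
})

setMethod("show", "RetentionEvent", function(object) {
  cat(sprintf("RetentionEvent: intron %d retained\n", object@intronIndex))
})

setMethod("show", "IsoformRecord", function(object) {
  lab <- eventLabel(object@event)
  cat(sprintf("IsoformRecord [%s]: %d nt mature, removed coding %s nt%s\n",
              lab, length(object@mature@sequence),
              object@removedCodingLength,
              if (isTRUE(object@startLost)) " (start lost)" else ""))
})

setMethod("show", "NmdVerdict", function(object) {
  cat(sprintf(
    "NmdVerdict: stop at %s, premature=%s, distance to last junction=%s nt, NMD substrate=%s\n",
    object@stopMrnaPos, object@isPremature,
    object@distanceToLastJunction, object@nmdSubstrate))
})
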