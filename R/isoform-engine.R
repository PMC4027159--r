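#' @importFrom IRanges IRanges restrict
NULL

# ---- event constructors -----------------------------------------------------

#' Construct mis-splicing events
#'
#' @param exonIndices contiguous 1-based indices of skipped internal exons.
#' @param exonIndex exon affected by a cryptic splice site.
#' @param newBoundary genomic position of the new exon boundary: the last
#'   retained exonic base for a cryptic donor, the first retained base for
#'   a cryptic acceptor (donor/acceptor in transcript orientation).
#' @param side `"donor"` (cryptic 5'ss) or `"acceptor"` (cryptic 3'ss).
#' @param intronIndex index of the retained intron (between exon
#'   `intronIndex` and `intronIndex + 1`).
#' @return a [SpliceEvent-classes] object.
#' @examples
#' skipEvent(2)        # skip exon 2
#' skipEvent(c(5, 6))  # contiguous double skip
#' @export
skipEvent <- function(exonIndices)
  new("SkipEvent", exonIndices = as.integer(sort(exonIndices)))

#' @rdname skipEvent
#' @export
crypticSpliceEvent <- function(exonIndex, newBoundary,
                               side = c("donor", "acceptor"))
  new("CrypticSpliceEvent", exonIndex = as.integer(exonIndex),
      newBoundary = as.integer(newBoundary), side = match.arg(side))

#' @rdname skipEvent
#' @export
retentionEvent <- function(intronIndex)
  new("RetentionEvent", intronIndex = as.integer(intronIndex))

# ---- event enumeration ------------------------------------------------------

#' Enumerate contiguous internal exon-skipping events
#'
#' All contiguous runs of internal exons (never the first or last exon) up
#' to `maxRun` exons long, ordered by (start index, run length). These are
#' the candidate outcomes of a splice-blocking ASO screen: single skips
#' plus the contiguous multi-exon skips occasionally observed (e.g. a
#' double skip of two adjacent exons).
#'
#' @param model a [TranscriptModel-class] with at least 3 exons.
#' @param maxRun maximum number of consecutively skipped exons (>= 1).
#' @return a list of [SpliceEvent-classes] `SkipEvent` objects (empty, with
#'   a warning, for models with fewer than 3 exons).
#' @export
enumerateSkips <- function(model, maxRun = 1L) {
  stopifnot(maxRun >= 1L)
  n <- length(model@exons)
  if (n < 3L) {
    warning("model '", model@transcriptId,
            "' has fewer than 3 exons; no internal exon can be skipped")
    return(list())
  }
  events <- list()
  for (s in 2:(n - 1L))
    for (len in seq_len(min(maxRun, n - s)))
      if (s + len - 1L <= n - 1L)
        events[[length(events) + 1L]] <- skipEvent(seq.int(s, s + len - 1L))
  events
}

# ---- applying events --------------------------------------------------------

# exon structure of the isoform produced by an event (IRanges, genomic)
editedExons <- function(model, event) {
  ex <- model@exons
  n <- length(ex)
  minus <- model@strand == "-"
  if (is.null(event)) return(ex)
  if (is(event, "SkipEvent")) {
    ix <- event@exonIndices
    if (any(ix < 2L) || any(ix > n - 1L))
      stop("skip event touches the first or last exon of a ", n,
           "-exon model", call. = FALSE)
    return(ex[-ix])
  }
  if (is(event, "CrypticSpliceEvent")) {
    i <- event@exonIndex
    if (i < 1L || i > n) stop("invalid exon index ", i, call. = FALSE)
    b <- event@newBoundary
    if (b <= start(ex)[i] || b >= end(ex)[i])
      stop("cryptic boundary ", b, " is not strictly inside exon ", i,
           " [", start(ex)[i], ", ", end(ex)[i], "]", call. = FALSE)
    # donor = transcript 3' end of the exon; genomic right end on '+',
    # genomic left end on '-'
    truncRight <- (event@side == "donor") != minus
    newEx <- if (truncRight) IRanges(start(ex)[i], b)
             else IRanges(b, end(ex)[i])
    out <- ex
    out[i] <- newEx
    return(out)
  }
  if (is(event, "RetentionEvent")) {
    i <- event@intronIndex
    if (i < 1L || i > n - 1L)
      stop("invalid intron index ", i, " for a ", n, "-exon model",
           call. = FALSE)
    merged <- IRanges(start(ex)[i], end(ex)[i + 1L])
    out <- c(ex[seq_len(i - 1L)], merged,
             if (i + 2L <= n) ex[seq.int(i + 2L, n)] else IRanges())
    return(out)
  }
  stop("unknown event class: ", class(event), call. = FALSE)
}

# TranscriptModel carrying the edited exon structure
editedModel <- function(model, event) {
  ex <- editedExons(model, event)
  m <- model
  m@exons <- ex
  # CDS endpoints may now fall outside exons (start/stop lost); keep the
  # genomic values but bypass validity for that transient state
  slot(m, "transcriptId", check = FALSE) <- paste0(model@transcriptId, "|",
                                                   eventLabel(event))
  m
}

#' Apply a mis-splicing event to a transcript
#'
#' Rebuilds the mature transcript with the event's exons removed,
#' truncated, or the retained intron spliced in; the junction chain and
#' CDS start are recomputed on the new isoform. When the event removes the
#' start codon the record is flagged `startLost` and excluded from frame
#' and NMD classification downstream.
#'
#' @param genome genomic sequence (as for [spliceTranscript()]).
#' @param model a [TranscriptModel-class].
#' @param event a [SpliceEvent-classes] object, or `NULL` for the
#'   reference isoform.
#' @return an [IsoformRecord-class].
#' @export
applyEvent <- function(genome, model, event = NULL) {
  ex <- model@exons
  newEx <- editedExons(model, event)
  em <- model
  em@exons <- newEx

  codingWidth <- function(x) {
    if (is.na(model@cdsStart)) return(NA_integer_)
    r <- restrict(x, model@cdsStart, model@cdsEnd)
    sum(width(r[width(r) > 0L]))
  }
  refCoding <- codingWidth(ex)
  newCoding <- codingWidth(newEx)
  removed <- if (is(event, "RetentionEvent") || is.null(event)) 0L
             else refCoding - newCoding
  added <- if (is(event, "RetentionEvent"))
    sum(width(newEx)) - sum(width(ex)) else 0L

  # first transcribed coding base (the A of the start codon)
  startBase <- if (model@strand == "+") model@cdsStart else model@cdsEnd
  startLost <- !is.na(startBase) &&
    !any(startBase >= start(newEx) & startBase <= end(newEx))

  id <- paste0(model@transcriptId, "|", eventLabel(event))
  mature <- spliceTranscript(genome, em, id = id)
  if (startLost) mature@cdsStartMrna <- NA_integer_
  new("IsoformRecord", event = event, mature = mature,
      removedCodingLength = as.integer(removed),
      addedLength = as.integer(added), startLost = startLost)
}

#' Does an event disrupt the reading frame?
#'
#' A skip or cryptic-splice isoform is frameshifted exactly when the
#' number of coding nucleotides it removed is not a multiple of 3. A
#' contiguous double skip removing, say, 70 + 80 coding nt is in frame.
#'
#' @param record an [IsoformRecord-class] from a skip or cryptic event
#'   whose start codon survived.
#' @return `TRUE` if the reading frame is disrupted.
#' @export
frameDisruption <- function(record) {
  if (isTRUE(record@startLost))
    stop("frame undefined: the event removed the start codon",
         call. = FALSE)
  if (is.null(record@event) || is(record@event, "RetentionEvent"))
    stop("frame disruption is defined for skip and cryptic-splice events",
         call. = FALSE)
  (record@removedCodingLength %% 3L) != 0L
}

# ---- ORF scan ---------------------------------------------------------------

#' Scan an isoform's open reading frame for the terminating stop
#'
#' Translates codon-by-codon from the annotated CDS start and reports the
#' first in-frame stop codon (TAA/TAG/TGA). No reinitiation or alternative
#' frames are considered: a codon created across a novel exon-exon
#' junction counts like any other because the scan runs on the final
#' isoform sequence.
#'
#' @param mature a [MatureTranscript-class] with a valid CDS start.
#' @return a list with `stopPos` (mRNA position of the first nucleotide of
#'   the stop codon, `NA` if none), `proteinLength` (codons before the
#'   stop), `noStop` (`TRUE` when translation runs off the transcript end)
#'   and `flaggedN` (`TRUE` when an `N` base fell inside the scanned
#'   region).
#' @export
scanOrf <- function(mature) {
  cs <- mature@cdsStartMrna
  if (is.na(cs)) stop("CDS start is undefined on this isoform",
                      call. = FALSE)
  seq <- as.character(mature@sequence)
  n <- nchar(seq)
  if (n < cs + 2L) stop("sequence too short for a single codon after cdsStart",
                        call. = FALSE)
  starts <- seq.int(cs, n - 2L, by = 3L)
  cods <- substring(seq, starts, starts + 2L)
  hit <- which(cods %in% STOP_CODONS)
  if (length(hit)) {
    stopPos <- starts[hit[1L]]
    scanned <- substr(seq, cs, stopPos + 2L)
    list(stopPos = stopPos, proteinLength = hit[1L] - 1L, noStop = FALSE,
         flaggedN = grepl("N", scanned, fixed = TRUE))
  } else {
    list(stopPos = NA_integer_, proteinLength = NA_integer_, noStop = TRUE,
         flaggedN = grepl("N", substr(seq, cs, n), fixed = TRUE))
  }
}

# ---- NMD classification -----------------------------------------------------

#' Configuration of the NMD last-junction rule
#'
#' A premature termination codon located strictly more than `thresholdNt`
#' nucleotides upstream of the last exon-exon junction marks the mRNA as a
#' likely NMD substrate. The distance is anchored at the first (5'-most)
#' nucleotide of the stop codon; the anchor is recorded here so the
#' convention travels with the verdicts.
#'
#' @param thresholdNt distance threshold in nucleotides (default 55).
#' @return a list with class `NmdRuleConfig`.
#' @export
nmdRuleConfig <- function(thresholdNt = 55L) {
  stopifnot(thresholdNt >= 0L)
  structure(list(thresholdNt = as.integer(thresholdNt),
                 distanceAnchor = "first_nt_of_stop"),
            class = "NmdRuleConfig")
}

#' Classify an isoform as an NMD substrate
#'
#' Applies the last-junction rule: the stop is premature when it differs
#' from the isoform-mapped reference stop, and the isoform is a predicted
#' NMD substrate when that premature stop lies strictly more than the
#' configured threshold upstream of the last exon-exon junction. A
#' junction-less (single-exon) isoform is never a substrate and its
#' distance is `NA`.
#'
#' @param mature the isoform, a [MatureTranscript-class].
#' @param stopMrnaPos mRNA position of the first nucleotide of the
#'   terminating stop (from [scanOrf()]).
#' @param referenceStop mRNA position, on this isoform, where the
#'   reference stop maps (`NA` when the reference stop no longer exists on
#'   the isoform).
#' @param config an [nmdRuleConfig()].
#' @param frameshift optional logical recorded on the verdict.
#' @return an [NmdVerdict-class].
#' @export
classifyNmd <- function(mature, stopMrnaPos, referenceStop,
                        config = nmdRuleConfig(), frameshift = NA) {
  stopifnot(inherits(config, "NmdRuleConfig"))
  stopMrnaPos <- as.integer(stopMrnaPos)
  if (is.na(stopMrnaPos))
    stop("no stop codon was found; cannot classify", call. = FALSE)
  premature <- is.na(referenceStop) || stopMrnaPos != as.integer(referenceStop)
  j <- mature@junctions
  if (!length(j)) {
    return(new("NmdVerdict", stopMrnaPos = stopMrnaPos,
               isPremature = premature, frameshift = as.logical(frameshift),
               distanceToLastJunction = NA_integer_, nmdSubstrate = FALSE))
  }
  distance <- j[length(j)] - stopMrnaPos
  new("NmdVerdict", stopMrnaPos = stopMrnaPos, isPremature = premature,
      frameshift = as.logical(frameshift),
      distanceToLastJunction = as.integer(distance),
      nmdSubstrate = premature && distance > config$thresholdNt)
}

# ---- design report ----------------------------------------------------------

#' Screen a transcript for NMD-inducing skip events
#'
#' Enumerates exon-skipping events (plus any extra events supplied),
#' applies each, scans the resulting open reading frame and classifies the
#' isoform under the NMD rule. This is the in-silico arm of an ASO
#' exon-skipping screen: rows where `frameshift` and `nmdSubstrate` are
#' both `TRUE` name the exons whose skipping should route the transcript
#' to degradation.
#'
#' @param genome genomic sequence (as for [spliceTranscript()]).
#' @param model a [TranscriptModel-class].
#' @param maxRun maximum contiguous skip run (see [enumerateSkips()]).
#' @param config an [nmdRuleConfig()].
#' @param events optional list of [SpliceEvent-classes] objects to use
#'   instead of the enumerated skips.
#' @return a `data.frame` with one row per event and columns `event`,
#'   `exons`, `frameshift`, `ptc_pos`, `distance_nt`, `nmd_substrate`,
#'   `start_lost`.
#' @export
designReport <- function(genome, model, maxRun = 1L,
                         config = nmdRuleConfig(), events = NULL) {
  if (is.null(events)) events <- enumerateSkips(model, maxRun)
  cols <- c("event", "exons", "frameshift", "ptc_pos", "distance_nt",
            "nmd_substrate", "start_lost")
  if (!length(events)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
    return(out)
  }
  refMature <- spliceTranscript(genome, model)
  refScan <- scanOrf(refMature)
  refStopGenomic <- if (is.na(refScan$stopPos)) NA_integer_
                    else mrnaToGenomic(model, refScan$stopPos)
  rows <- lapply(events, function(ev) {
    rec <- applyEvent(genome, model, ev)
    lab <- eventLabel(ev)
    exonsField <- if (is(ev, "SkipEvent"))
      paste(ev@exonIndices, collapse = "+") else NA_character_
    if (isTRUE(rec@startLost)) {
      return(data.frame(event = lab, exons = exonsField, frameshift = NA,
                        ptc_pos = NA_integer_, distance_nt = NA_integer_,
                        nmd_substrate = NA, start_lost = TRUE,
                        stringsAsFactors = FALSE))
    }
    fs <- if (is(ev, "RetentionEvent")) NA else frameDisruption(rec)
    scan <- scanOrf(rec@mature)
    if (is.na(scan$stopPos)) {
      return(data.frame(event = lab, exons = exonsField, frameshift = fs,
                        ptc_pos = NA_integer_, distance_nt = NA_integer_,
                        nmd_substrate = FALSE, start_lost = FALSE,
                        stringsAsFactors = FALSE))
    }
    em <- editedModel(model, ev)
    mappedRef <- if (is.na(refStopGenomic)) NA_integer_ else {
      span <- range(start(em@exons)[1L], end(em@exons)[length(em@exons)])
      if (refStopGenomic < span[1L] || refStopGenomic > span[2L])
        NA_integer_
      else genomicToMrna(em, refStopGenomic)
    }
    v <- classifyNmd(rec@mature, scan$stopPos, mappedRef, config,
                     frameshift = fs)
    data.frame(event = lab, exons = exonsField, frameshift = fs,
               ptc_pos = v@stopMrnaPos,
               distance_nt = v@distanceToLastJunction,
               nmd_substrate = v@nmdSubstrate, start_lost = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a design report as TSV
#'
#' @param report a `data.frame` from [designReport()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDesignReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
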