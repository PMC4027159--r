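#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges pintersect
NULL

#' Tiling configuration for an ASO walk
#'
#' Defaults reproduce an unbiased splice-switching screen: 18-mer ASOs
#' spaced every 3 nt across the target exon and its flanking splice sites.
#' `flank` controls how far the tiling window reaches into each adjacent
#' intron; with the default 18/3/15 geometry every junction-spanning
#' candidate keeps at least 3 exonic nucleotides.
#'
#' @param asoLength candidate length in nt (default 18).
#' @param step spacing between consecutive candidate starts (default 3).
#' @param flank nucleotides of intron included on each side of the exon
#'   (default 15); must be smaller than `asoLength` so every candidate
#'   overlaps the exon.
#' @return a list with class `TilingConfig`.
#' @export
tilingConfig <- function(asoLength = 18L, step = 3L, flank = 15L) {
  asoLength <- as.integer(asoLength); step <- as.integer(step)
  flank <- as.integer(flank)
  if (step < 1L || step > asoLength)
    stop("step must satisfy 1 <= step <= asoLength", call. = FALSE)
  if (flank < 0L || flank >= asoLength)
    stop("flank must satisfy 0 <= flank < asoLength", call. = FALSE)
  structure(list(asoLength = asoLength, step = step, flank = flank),
            class = "TilingConfig")
}

#' Tile ASO candidates across an exon and its splice sites
#'
#' Walks a window `[exon start - flank, exon end + flank]` on the pre-mRNA
#' in transcript orientation, emitting one antisense candidate per step.
#' Each candidate records its sense-target genomic interval, the antisense
#' sequence written 5' to 3', whether it spans the 5' (donor) or 3'
#' (acceptor) splice site, and how many of its bases are exonic.
#'
#' @param genome genomic sequence (as for [spliceTranscript()]).
#' @param model a [TranscriptModel-class].
#' @param exonIndex index of the target exon.
#' @param config a [tilingConfig()].
#' @return a [GenomicRanges::GRanges] of sense-target intervals, strand
#'   set to the ASO (antisense) strand, with metadata columns `id`,
#'   `transcript`, `exon`, `offset`, `asoSequence`, `overlaps5ss`,
#'   `overlaps3ss`, `exonOverlapNt`, `chemistry`, `sugars`, `backbone`.
#'   Rows are ordered 5' to 3' along the transcript.
#' @export
tileAso <- function(genome, model, exonIndex, config = tilingConfig()) {
  stopifnot(inherits(config, "TilingConfig"))
  seq <- resolveGenomeSeq(genome, model)
  ex <- model@exons
  if (exonIndex < 1L || exonIndex > length(ex))
    stop("exonIndex ", exonIndex, " out of range for a ", length(ex),
         "-exon model", call. = FALSE)
  L <- config$asoLength
  wStart <- start(ex)[exonIndex] - config$flank
  wEnd <- end(ex)[exonIndex] + config$flank
  if (wStart < 1L || wEnd > nchar(seq))
    stop("tiling window [", wStart, ", ", wEnd, "] exceeds sequence ",
         "bounds [1, ", nchar(seq), "]; reduce flank or extend the ",
         "sequence (no silent clipping)", call. = FALSE)
  wLen <- wEnd - wStart + 1L
  if (wLen < L)
    stop("tiling window (", wLen, " nt) is shorter than the ASO length (",
         L, " nt)", call. = FALSE)
  nCand <- (wLen - L) %/% config$step + 1L
  offs <- (seq_len(nCand) - 1L) * config$step
  minus <- model@strand == "-"
  # enumerate from the transcript 5' end of the window
  gStart <- if (minus) wEnd - L + 1L - offs else wStart + offs
  gEnd <- gStart + L - 1L

  sense <- substring(seq, gStart, gEnd)
  if (minus) sense <- vapply(sense, revComp, character(1), USE.NAMES = FALSE)
  aso <- vapply(sense, revComp, character(1), USE.NAMES = FALSE)

  exS <- start(ex)[exonIndex]; exE <- end(ex)[exonIndex]
  hasLeft <- exonIndex > 1L        # genomic-left boundary has an intron
  hasRight <- exonIndex < length(ex)
  spansLeft <- hasLeft & gStart <= exS - 1L & gEnd >= exS
  spansRight <- hasRight & gStart <= exE & gEnd >= exE + 1L
  # 5'ss (donor) is the transcript-3' end of the exon
  overlaps5ss <- if (minus) spansLeft else spansRight
  overlaps3ss <- if (minus) spansRight else spansLeft
  exonOverlap <- pmax(0L, pmin(gEnd, exE) - pmax(gStart, exS) + 1L)

  ids <- sprintf("%s_e%d_%d", model@transcriptId, exonIndex, offs)
  gr <- GRanges(model@seqId, IRanges(gStart, gEnd),
                strand = if (minus) "+" else "-")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = ids, transcript = model@transcriptId, exon = as.integer(exonIndex),
    offset = offs, asoSequence = aso, overlaps5ss = overlaps5ss,
    overlaps3ss = overlaps3ss, exonOverlapNt = exonOverlap,
    chemistry = NA_character_, sugars = NA_character_,
    backbone = NA_character_)
  gr
}

#' Per-position chemistry profiles
#'
#' `chemistryProfile` builds the per-position sugar pattern for a named
#' chemistry; `applyChemistry` stamps it onto every tiled candidate.
#' Available profiles:
#' \describe{
#'   \item{`uniform_moe`}{every position 2'-MOE — a steric blocker that
#'     supports neither RNase H nor RISC.}
#'   \item{`gapmer_5_10_5`}{20-mer with five 2'-MOE wings flanking a
#'     ten-deoxy gap that supports RNase H cleavage.}
#'   \item{`uniform_2ome`}{every position 2'-O-methyl.}
#'   \item{`cet_mixmer`}{alternating 2',4'-constrained-ethyl and DNA
#'     positions, starting cEt (this package's mixmer convention).}
#'   \item{`custom`}{caller-supplied `sugars` vector.}
#' }
#' The backbone defaults to full phosphorothioate (`PS` at every linkage).
#'
#' @param name profile name.
#' @param length candidate length the profile must cover.
#' @param sugars for `custom`, a character vector over
#'   `{MOE, DNA, 2OMe, cEt}` of length `length`.
#' @return a list with `name`, `sugars` (length `length`) and `backbone`
#'   (length `length - 1`).
#' @examples
#' chemistryProfile("gapmer_5_10_5", 20)$sugars
#' @export
chemistryProfile <- function(name = c("uniform_moe", "gapmer_5_10_5",
                                      "uniform_2ome", "cet_mixmer",
                                      "custom"),
                             length, sugars = NULL) {
  name <- match.arg(name)
  length <- as.integer(length)
  sug <- switch(name,
    uniform_moe = rep("MOE", length),
    uniform_2ome = rep("2OMe", length),
    cet_mixmer = rep_len(c("cEt", "DNA"), length),
    gapmer_5_10_5 = {
      if (length != 20L)
        stop("gapmer_5_10_5 requires length 20, got ", length,
             call. = FALSE)
      c(rep("MOE", 5L), rep("DNA", 10L), rep("MOE", 5L))
    },
    custom = {
      if (is.null(sugars) || base::length(sugars) != length)
        stop("custom profile needs a 'sugars' vector of length ", length,
             call. = FALSE)
      bad <- setdiff(sugars, c("MOE", "DNA", "2OMe", "cEt"))
      if (base::length(bad))
        stop("unknown sugar(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      as.character(sugars)
    })
  list(name = name, sugars = sug,
       backbone = rep("PS", max(0L, length - 1L)))
}

#' @rdname chemistryProfile
#' @param candidates a `GRanges` from [tileAso()].
#' @return `applyChemistry`: the candidates with `chemistry`, `sugars` and
#'   `backbone` metadata columns filled.
#' @export
applyChemistry <- function(candidates, name = "uniform_moe",
                           sugars = NULL) {
  lens <- nchar(candidates$asoSequence)
  if (length(unique(lens)) != 1L)
    stop("candidates have mixed lengths; apply chemistry per subset",
         call. = FALSE)
  prof <- chemistryProfile(name, lens[1L], sugars = sugars)
  candidates$chemistry <- prof$name
  candidates$sugars <- paste(prof$sugars, collapse = ",")
  candidates$backbone <- paste(prof$backbone, collapse = ",")
  candidates
}

# ---- candidate I/O ----------------------------------------------------------

#' Write and read ASO candidate files
#'
#' `tsv` carries every field and round-trips through `readCandidates`;
#' `bed` is BED6 on the sense-target genomic interval (0-based half-open,
#' strand column = the ASO strand, i.e. antisense to the transcript);
#' `fasta` holds the antisense 5'-to-3' candidate sequences.
#'
#' @param candidates a `GRanges` from [tileAso()].
#' @param path output path.
#' @param format `"tsv"`, `"bed"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(candidates, path,
                            format = c("tsv", "bed", "fasta")) {
  format <- match.arg(format)
  if (!length(candidates))
    stop("no candidates to write", call. = FALSE)
  if (format == "tsv") {
    df <- data.frame(
      seqId = as.character(seqnames(candidates)),
      start = start(candidates), end = end(candidates),
      asoStrand = as.character(strand(candidates)),
      as.data.frame(S4Vectors::mcols(candidates)),
      stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     as.character(seqnames(candidates)),
                     start(candidates) - 1L, end(candidates),
                     candidates$id, as.character(strand(candidates)))
    writeLines(lines, path)
  } else {
    seqs <- Biostrings::DNAStringSet(candidates$asoSequence)
    names(seqs) <- candidates$id
    writeXStringSet(seqs, path)
  }
  invisible(path)
}

#' @rdname writeCandidates
#' @export
readCandidates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- GRanges(df$seqId, IRanges(df$start, df$end),
                strand = df$asoStrand)
  meta <- df[, setdiff(names(df), c("seqId", "start", "end", "asoStrand")),
             drop = FALSE]
  for (col in c("chemistry", "sugars", "backbone"))
    if (col %in% names(meta)) meta[[col]] <- as.character(meta[[col]])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  gr
}
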