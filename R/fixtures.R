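#' @importFrom Biostrings DNAStringSet
NULL

#' Specification of a synthetic multi-exon protein-coding locus
#'
#' Describes the exon/intron geometry of a locus the generator will
#' realize with random sequence: a controlled stand-in for the multi-exon
#' architecture of a real ASO target gene, with the coding frame and stop
#' placement fully determined so every downstream classification has a
#' known truth value.
#'
#' @param nExons number of exons (>= 3 recommended so internal exons can
#'   be skipped).
#' @param exonLengths,intronLengths integer vectors of lengths in nt
#'   (`nExons` and `nExons - 1` long).
#' @param cdsStartExon exon carrying the start codon (default 1).
#' @param cdsOffset 1-based position of the A of the start codon within
#'   that exon (default 10).
#' @param seed RNG seed; generation is bit-for-bit reproducible.
#' @param strand `"+"` or `"-"`.
#' @param id transcript identifier stem.
#' @return a list with class `LocusSpec`.
#' @export
locusSpec <- function(nExons, exonLengths, intronLengths,
                      cdsStartExon = 1L, cdsOffset = 10L, seed = 1L,
                      strand = "+", id = "syn_tx") {
  nExons <- as.integer(nExons)
  exonLengths <- as.integer(exonLengths)
  intronLengths <- as.integer(intronLengths)
  if (length(exonLengths) != nExons)
    stop("need ", nExons, " exon lengths", call. = FALSE)
  if (length(intronLengths) != nExons - 1L)
    stop("need ", nExons - 1L, " intron lengths", call. = FALSE)
  if (any(exonLengths < 1L) || any(intronLengths < 1L))
    stop("all lengths must be >= 1", call. = FALSE)
  if (cdsStartExon < 1L || cdsStartExon > nExons)
    stop("cdsStartExon out of range", call. = FALSE)
  if (cdsOffset < 1L || cdsOffset > exonLengths[cdsStartExon])
    stop("cdsOffset outside exon ", cdsStartExon, call. = FALSE)
  stopifnot(strand %in% c("+", "-"))
  structure(list(nExons = nExons, exonLengths = exonLengths,
                 intronLengths = intronLengths,
                 cdsStartExon = as.integer(cdsStartExon),
                 cdsOffset = as.integer(cdsOffset),
                 seed = as.integer(seed), strand = strand, id = id),
            class = "LocusSpec")
}

# assemble genome, model and truth table from finished exon/intron strings
assembleLocus <- function(spec, exonSeqs, intronSeqs, csMrna, stopMrna) {
  nEx <- length(exonSeqs)
  exonLengths <- nchar(exonSeqs)
  pieces <- character(2L * nEx - 1L)
  pieces[seq(1L, by = 2L, length.out = nEx)] <- exonSeqs
  if (nEx > 1L)
    pieces[seq(2L, by = 2L, length.out = nEx - 1L)] <- intronSeqs
  genomeSeq <- paste(pieces, collapse = "")
  gaps <- if (nEx > 1L) utils::head(exonLengths, -1L) + nchar(intronSeqs)
          else integer(0)
  exStarts <- cumsum(c(1L, gaps))
  exEnds <- exStarts + exonLengths - 1L
  seqId <- paste0(spec$id, "_locus")

  modelPlus <- transcriptModel(spec$id, paste0(spec$id, "_gene"), seqId,
                               "+", IRanges(exStarts, exEnds),
                               cdsStart = 1L, cdsEnd = 1L)
  # place genomic CDS endpoints from the mRNA truth
  cdsG <- sort(c(mrnaToGenomic(modelPlus, csMrna),
                 mrnaToGenomic(modelPlus, stopMrna + 2L)))
  modelPlus@cdsStart <- cdsG[1L]; modelPlus@cdsEnd <- cdsG[2L]
  validObject(modelPlus)

  if (spec$strand == "-") {
    G <- nchar(genomeSeq)
    genomeSeq <- revComp(genomeSeq)
    newStarts <- G - exEnds + 1L
    newEnds <- G - exStarts + 1L
    o <- order(newStarts)
    model <- transcriptModel(spec$id, paste0(spec$id, "_gene"), seqId,
                             "-", IRanges(newStarts[o], newEnds[o]),
                             cdsStart = G - cdsG[2L] + 1L,
                             cdsEnd = G - cdsG[1L] + 1L)
  } else {
    model <- modelPlus
  }
  genome <- DNAStringSet(genomeSeq)
  names(genome) <- seqId

  # per-exon truth: coding content and frame phase at exon entry
  bounds <- cumsum(exonLengths)
  exFromM <- c(1L, utils::head(bounds, -1L) + 1L)
  codingNt <- pmax(0L, pmin(bounds, stopMrna + 2L) -
                     pmax(exFromM, csMrna) + 1L)
  cumBefore <- cumsum(c(0L, utils::head(codingNt, -1L)))
  truthTable <- data.frame(
    exon = seq_len(nEx), length = exonLengths,
    genomicStart = start(model@exons), genomicEnd = end(model@exons),
    codingNt = codingNt, cumCodingBefore = cumBefore,
    phase = cumBefore %% 3L)
  list(genome = genome, model = model,
       truth = list(spec = spec, cdsStartMrna = csMrna,
                    stopMrna = stopMrna, exonTable = truthTable))
}

randomIntron <- function(len) {
  if (len >= 4L) paste0("GT", randomDna(len - 4L), "AG") else randomDna(len)
}

#' Generate a synthetic locus with controlled coding structure
#'
#' Realizes a [locusSpec()]: random coding sequence built codon-by-codon
#' with stop codons rejected, a guaranteed in-frame stop in the last exon,
#' and no premature in-frame stop anywhere in the reference mature mRNA.
#' Introns carry canonical GT...AG ends. The construction is verified
#' internally by splicing the model and scanning its open reading frame.
#'
#' @param spec a [locusSpec()].
#' @return a list with `genome` (named [Biostrings::DNAStringSet]),
#'   `model` (a [TranscriptModel-class]) and `truth` (the locus spec, the mRNA
#'   CDS start and stop positions, and a per-exon table of coding content
#'   and frame phase).
#' @export
makeLocus <- function(spec) {
  stopifnot(inherits(spec, "LocusSpec"))
  set.seed(spec$seed)
  total <- sum(spec$exonLengths)
  cs <- sum(spec$exonLengths[seq_len(spec$cdsStartExon - 1L)]) +
    spec$cdsOffset
  lastStart <- total - spec$exonLengths[spec$nExons] + 1L
  # stop roughly centered in the last exon, frame-aligned to cs
  target <- lastStart + max(0L, (spec$exonLengths[spec$nExons] - 3L) %/% 2L)
  q <- target - ((target - cs) %% 3L)
  if (q < lastStart) q <- q + 3L
  if (q < cs + 3L || q + 2L > total)
    stop("impossible constraints: no frame-aligned stop position fits in ",
         "the last exon (CDS start ", cs, ", mature length ", total, ")",
         call. = FALSE)
  mature <- paste0(randomDna(cs - 1L), nonStopCodons((q - cs) %/% 3L),
                   "TAA", randomDna(total - q - 2L))
  bounds <- cumsum(spec$exonLengths)
  exonSeqs <- substring(mature, c(1L, utils::head(bounds, -1L) + 1L), bounds)
  intronSeqs <- vapply(spec$intronLengths, randomIntron, character(1))
  locus <- assembleLocus(spec, exonSeqs, intronSeqs, cs, q)

  # closed-loop check: the engine recovers the embedded truth
  ref <- spliceTranscript(locus$genome, locus$model)
  scan <- scanOrf(ref)
  if (!identical(ref@cdsStartMrna, cs) || !identical(scan$stopPos, q))
    stop("internal error: constructed locus failed verification")
  locus
}

#' Boundary family for the NMD distance rule
#'
#' For each requested distance `d`, constructs a 4-exon locus in which
#' skipping internal exon 2 (100 nt, frameshifting) creates an isoform
#' whose first in-frame stop lies exactly `d` nucleotides (first-nt
#' anchor) upstream of the isoform's last exon-exon junction. Exon
#' geometry is held fixed except for the minimal length adjustment that
#' keeps the stop frame-aligned, so the family isolates the distance
#' variable; the reference transcript always carries its stop in the last
#' exon with no premature stop. Each member is verified by running the
#' isoform engine before it is returned.
#'
#' @param distances integer distances in nt (>= 0).
#' @param seed RNG seed.
#' @return a named list (`d<distance>`) of loci as returned by
#'   [makeLocus()]; each `truth` additionally records `distance` and the
#'   expected PTC position `ptcMrna` on the skipped isoform.
#' @export
makeNmdBoundaryFamily <- function(distances, seed = 1L) {
  distances <- as.integer(distances)
  if (any(distances < 0L))
    stop("distances must be >= 0", call. = FALSE)
  set.seed(seed)
  out <- lapply(distances, function(d) buildBoundaryLocus(d, seed))
  names(out) <- paste0("d", distances)
  out
}

# one member of the boundary family; uses the current RNG stream
buildBoundaryLocus <- function(d, seed) {
  cs <- 10L; L1 <- 120L; L2 <- 100L
  L3 <- 90L + ((d - 90L) %% 3L)        # keeps the PTC frame-aligned
  if (d > L3)
    stop("distance ", d, " nt unachievable with this geometry (exon 3 is ",
         L3, " nt)", call. = FALSE)
  # skipped isoform: exons 1+3+4; last junction at L1+L3+1, PTC first nt at
  p <- L1 + L3 + 1L - d

  for (try in seq_len(500L)) {
    e1 <- paste0(randomDna(cs - 1L), nonStopCodons((L1 - cs + 1L) %/% 3L))
    # exon 3 content written in the frameshifted (skipped) frame
    t3 <- paste0(nonStopCodons((L3 - d) %/% 3L), "TAA",
                 randomDna(max(0L, d - 3L)))
    e3 <- substr(t3, 1L, L3)
    overflow <- if (nchar(t3) > L3) substr(t3, L3 + 1L, nchar(t3)) else ""
    # exon 2: 100 nt of reference-frame coding (33 codons + 1 nt)
    e2 <- paste0(nonStopCodons(33L), randomDna(1L))
    # the reference frame reads straight through e2|e3|overflow; reject
    # attempts where the fixed frameshifted content creates a stop there
    if (length(frameStops(paste0(e2, e3, overflow), 1L))) next
    consumed <- nchar(e2) + nchar(e3) + nchar(overflow)
    rem <- consumed %% 3L
    carry <- (3L - rem) %% 3L
    completion <- ""
    if (carry > 0L) {
      prefix <- substr(paste0(e2, e3, overflow), consumed - rem + 1L,
                       consumed)
      repeat {
        completion <- randomDna(carry)
        if (!paste0(prefix, completion) %in% STOP_CODONS) break
      }
    }
    e4 <- paste0(overflow, completion, nonStopCodons(20L), "TAA",
                 randomDna(60L))
    spec <- locusSpec(4L, c(L1, L2, L3, nchar(e4)),
                      intronLengths = c(150L, 120L, 100L),
                      cdsStartExon = 1L, cdsOffset = cs, seed = seed,
                      strand = "+", id = sprintf("nmd_d%02d", d))
    qRef <- L1 + L2 + L3 + nchar(overflow) + carry + 60L + 1L
    introns <- vapply(spec$intronLengths, randomIntron, character(1))
    locus <- assembleLocus(spec, c(e1, e2, e3, e4), introns, cs, qRef)

    # verify with the engine: reference clean, skipped PTC at distance d
    refScan <- scanOrf(spliceTranscript(locus$genome, locus$model))
    rec <- applyEvent(locus$genome, locus$model, skipEvent(2L))
    skipScan <- scanOrf(rec@mature)
    j <- rec@mature@junctions
    if (identical(refScan$stopPos, qRef) &&
        identical(skipScan$stopPos, p) &&
        identical(j[length(j)] - p, d)) {
      locus$truth$distance <- d
      locus$truth$ptcMrna <- p
      return(locus)
    }
  }
  stop("internal error: boundary locus construction failed for d = ", d)
}

#' Generate assay fixtures with embedded truth values
#'
#' Builds internally consistent inputs for the quantification and ESE
#' modules: gel lanes constructed from a chosen molar skipping fraction,
#' a qPCR dilution series on a chosen standard curve with unknowns of
#' known relative quantity, a set of 28 5' RACE clones drawn from three
#' chosen cleavage positions on a synthetic transcript, and a synthetic
#' PWM file with a motif planted at a known offset. When `dir` is given
#' the fixtures are also written as plain-text files (TSV/FASTA; the seed
#' is recorded in each file header).
#'
#' @param seed RNG seed.
#' @param dir optional output directory.
#' @return a list of fixtures and their truth values (and `paths` when
#'   written).
#' @export
makeAssayFixtures <- function(seed = 1L, dir = NULL) {
  set.seed(seed)
  # gel: molar fraction 0.25 skipped; intensities follow mass = molar * bp
  gel <- list(
    lanes = data.frame(
      label = c("inclusion", "exclusion"),
      intensity = c(3 * 404, 1 * 304),
      length_bp = c(404L, 304L)),
    truthPercent = 25)

  # qPCR: curve ct = -3.32 * log10(q) + 20; unknowns at known quantities
  slope <- -3.32; intercept <- 20
  cq <- 10^seq(0, -3)
  unknownQ <- c(control = 1, aso = 0.25)
  qpcr <- list(
    curve = data.frame(quantity = cq,
                       ct = intercept + slope * log10(cq)),
    unknowns = data.frame(sample = names(unknownQ),
                          ct = intercept + slope * log10(unknownQ)),
    truth = list(slope = slope, intercept = intercept,
                 quantities = unknownQ))

  # RACE: 28 clones from three cleavage positions (cf. heterogeneous 5'
  # ends clustered near the PTC)
  locus <- makeLocus(locusSpec(4L, c(120L, 100L, 90L, 140L),
                               c(150L, 120L, 100L), seed = seed + 7L,
                               id = "race_tx"))
  mature <- spliceTranscript(locus$genome, locus$model)
  positions <- c(150L, 163L, 171L)
  countsPer <- c(20L, 5L, 3L)
  cloneLen <- 60L
  mseq <- as.character(mature@sequence)
  clones <- unlist(lapply(seq_along(positions), function(i)
    setNames(rep(substr(mseq, positions[i], positions[i] + cloneLen - 1L),
                 countsPer[i]),
             sprintf("cleavage_%d_clone%02d", positions[i],
                     seq_len(countsPer[i])))))
  race <- list(clones = clones, mature = mature,
               truth = setNames(countsPer, positions))

  # PWM with a planted motif
  motif <- "GAAGAAG"
  mb <- strsplit(motif, "")[[1L]]
  w <- matrix(0, 4L, nchar(motif), dimnames = list(DNA_BASES, NULL))
  w[cbind(match(mb, DNA_BASES), seq_along(mb))] <- 2
  synPwm <- pwm("SYN_SR1", w, threshold = 2 * nchar(motif))
  plantOffset <- 31L
  eseSeq <- paste0(randomDna(plantOffset - 1L), motif, randomDna(42L))
  ese <- list(pwm = synPwm, sequence = eseSeq, plantOffset = plantOffset,
              motif = motif)

  out <- list(gel = gel, qpcr = qpcr, race = race, ese = ese, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hdr <- sprintf("# seed=%d", seed)
    writeTsv <- function(df, file) {
      path <- file.path(dir, file)
      writeLines(hdr, path)
      suppressWarnings(utils::write.table(df, path, sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          append = TRUE))
      path
    }
    paths <- list(
      lanes = writeTsv(gel$lanes, "gel_lanes.tsv"),
      curve = writeTsv(qpcr$curve, "qpcr_curve.tsv"),
      unknowns = writeTsv(qpcr$unknowns, "qpcr_unknowns.tsv"))
    cloneSet <- DNAStringSet(clones)
    names(cloneSet)[1L] <- paste0(names(cloneSet)[1L], " seed=", seed)
    paths$clones <- file.path(dir, "race_clones.fa")
    writeXStringSet(cloneSet, paths$clones)
    paths$pwm <- file.path(dir, "pwm_matrices.tsv")
    tmp <- tempfile()
    writePwm(list(synPwm), tmp)
    writeLines(c(hdr, "# synthetic example matrices, not published motifs",
                 readLines(tmp)), paths$pwm)
    unlink(tmp)
    mat <- DNAStringSet(setNames(mseq, paste0("race_tx seed=", seed)))
    paths$transcript <- file.path(dir, "race_transcript.fa")
    writeXStringSet(mat, paths$transcript)
    eseFa <- DNAStringSet(setNames(eseSeq,
      sprintf("ese_example planted=%s offset=%d seed=%d", motif,
              plantOffset, seed)))
    paths$ese <- file.path(dir, "ese_example.fa")
    writeXStringSet(eseFa, paths$ese)
    out$paths <- paths
  }
  out
}
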