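# brute-force enumeration of contiguous internal runs, independent of the
# implementation's loop
oracleSkipRuns <- function(nExons, maxRun) {
  runs <- list()
  for (s in 2:(nExons - 1))
    for (e in s:(nExons - 1))
      if (e - s + 1 <= maxRun) runs[[length(runs) + 1]] <- s:e
  runs
}

test_that("enumerateSkips lists contiguous internal runs deterministically", {
  loc <- makeLocus(locusSpec(5, c(120, 100, 90, 110, 140),
                             c(150, 120, 100, 130), seed = 1))
  ev1 <- enumerateSkips(loc$model, maxRun = 1)
  expect_identical(lapply(ev1, function(e) e@exonIndices),
                   list(2L, 3L, 4L))
  ev2 <- enumerateSkips(loc$model, maxRun = 2)
  expect_length(ev2, 5L)
  got <- lapply(ev2, function(e) e@exonIndices)
  want <- oracleSkipRuns(5, 2)
  expect_setequal(lapply(got, paste, collapse = "+"),
                  lapply(want, paste, collapse = "+"))
  # ordered by (start index, run length)
  keys <- t(vapply(got, function(x) c(x[1], length(x)), numeric(2)))
  expect_false(is.unsorted(order(keys[, 1], keys[, 2])))
  expect_identical(order(keys[, 1], keys[, 2]), seq_len(nrow(keys)))

  # an 8-exon model at maxRun 2 includes the 5+6 double skip
  loc8 <- makeLocus(locusSpec(8, rep(90, 8), rep(100, 7), seed = 2))
  got8 <- lapply(enumerateSkips(loc8$model, 2), function(e) e@exonIndices)
  expect_true(any(vapply(got8, identical, TRUE, c(5L, 6L))))
})

test_that("models with fewer than 3 exons yield no skips, with a warning", {
  m <- transcriptModel("t", "g", "chr", "+",
                       IRanges::IRanges(c(1, 20), c(10, 30)), 1, 30)
  expect_warning(ev <- enumerateSkips(m), "fewer than 3")
  expect_length(ev, 0L)
})

test_that("applyEvent rebuilds mature, junctions and removed lengths", {
  loc <- makeLocus(locusSpec(3, c(30, 40, 30), c(100, 100),
                             cdsOffset = 4, seed = 5))
  ref <- spliceTranscript(loc$genome, loc$model)
  rec <- applyEvent(loc$genome, loc$model, skipEvent(2))
  expect_identical(length(mrnaSequence(rec@mature)), 60L)
  expect_identical(junctions(rec@mature), 31L)

  # intron retention: length grows by the intron, one junction disappears
  ret <- applyEvent(loc$genome, loc$model, retentionEvent(1))
  expect_identical(length(mrnaSequence(ret@mature)),
                   length(mrnaSequence(ref)) + 100L)
  expect_identical(ret@addedLength, 100L)
  expect_identical(length(junctions(ret@mature)),
                   length(junctions(ref)) - 1L)

  # cryptic donor 10 nt before the exon end: verified against an
  # independent re-splice with an edited exon list
  ex <- exons(loc$model)
  b <- BiocGenerics::end(ex)[2] - 10L
  cry <- applyEvent(loc$genome, loc$model,
                    crypticSpliceEvent(2, b, "donor"))
  starts <- BiocGenerics::start(ex); ends <- BiocGenerics::end(ex)
  ends[2] <- b
  expect_identical(as.character(mrnaSequence(cry@mature)),
                   oracleSplice(as.character(loc$genome[[1]]), starts,
                                ends, "+"))
  expect_identical(length(mrnaSequence(cry@mature)),
                   length(mrnaSequence(ref)) - 10L)
  expect_error(applyEvent(loc$genome, loc$model,
                          crypticSpliceEvent(2, BiocGenerics::end(ex)[2],
                                             "donor")),
               "strictly inside")
})

test_that("frameDisruption follows removed coding length mod 3", {
  # exon 2 fully coding: 100 nt removed -> shift; 99 nt -> in frame
  locA <- makeLocus(locusSpec(3, c(60, 100, 90), c(80, 80), seed = 6))
  recA <- applyEvent(locA$genome, locA$model, skipEvent(2))
  expect_identical(recA@removedCodingLength, 100L)
  expect_true(frameDisruption(recA))

  locB <- makeLocus(locusSpec(3, c(60, 99, 90), c(80, 80), seed = 6))
  recB <- applyEvent(locB$genome, locB$model, skipEvent(2))
  expect_false(frameDisruption(recB))

  # contiguous double skip of 70 + 80 coding nt stays in frame
  locC <- makeLocus(locusSpec(4, c(60, 70, 80, 90), c(50, 50, 50),
                              seed = 7))
  recC <- applyEvent(locC$genome, locC$model, skipEvent(c(2, 3)))
  expect_identical(recC@removedCodingLength, 150L)
  expect_false(frameDisruption(recC))
})

test_that("events that remove the start codon are flagged, not classified", {
  # CDS starts in exon 2 of a 4-exon model, so skipping exon 2 loses it
  loc <- makeLocus(locusSpec(4, c(60, 80, 90, 100), c(70, 70, 70),
                             cdsStartExon = 2, cdsOffset = 10, seed = 8))
  rec <- applyEvent(loc$genome, loc$model, skipEvent(2))
  expect_true(rec@startLost)
  expect_true(is.na(cdsStartMrna(rec@mature)))
  expect_error(frameDisruption(rec), "start codon")
  rep <- designReport(loc$genome, loc$model, maxRun = 1)
  expect_true(rep$start_lost[rep$exons == "2"])
  expect_true(is.na(rep$nmd_substrate[rep$exons == "2"]))
})

test_that("scanOrf finds the first in-frame stop", {
  mk <- function(seq, cs) new("MatureTranscript", transcriptId = "t",
                              sequence = Biostrings::DNAString(seq),
                              junctions = integer(),
                              cdsStartMrna = as.integer(cs),
                              exonProvenance = 1L)
  expect_identical(scanOrf(mk("ATGAAATAG", 1))$stopPos, 7L)
  expect_identical(scanOrf(mk("ATGAAATAG", 1))$proteinLength, 2L)
  expect_identical(scanOrf(mk("ATGTGACCC", 1))$stopPos, 4L)
  noStop <- scanOrf(mk("ATGAAACCC", 1))
  expect_true(noStop$noStop)
  expect_true(is.na(noStop$stopPos))
  expect_true(scanOrf(mk("ATGANATAG", 1))$flaggedN)

  set.seed(99)
  for (i in 1:50) {
    n <- sample(30:200, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    cs <- sample(1:5, 1)
    if (n - cs + 1 < 3) next
    expect_identical(scanOrf(mk(seq, cs))$stopPos,
                     oracleFirstStop(seq, cs))
  }
})

test_that("classifyNmd applies the strict >55 nt last-junction rule", {
  mk <- function(len, junc) new("MatureTranscript", transcriptId = "t",
                                sequence = Biostrings::DNAString(
                                  strrep("A", len)),
                                junctions = as.integer(junc),
                                cdsStartMrna = 1L,
                                exonProvenance = 1L)
  m <- mk(400, c(100, 300))
  expect_true(classifyNmd(m, 300L - 56L, 390L)@nmdSubstrate)
  expect_false(classifyNmd(m, 300L - 55L, 390L)@nmdSubstrate)
  # a stop downstream of the last junction is never a substrate
  v <- classifyNmd(m, 310L, 390L)
  expect_true(v@distanceToLastJunction < 0L)
  expect_false(v@nmdSubstrate)
  # the reference stop itself is not premature
  expect_false(classifyNmd(m, 390L, 390L)@isPremature)
  # junction-less isoform: no rule to apply
  v1 <- classifyNmd(mk(400, integer()), 100L, 390L)
  expect_false(v1@nmdSubstrate)
  expect_true(is.na(v1@distanceToLastJunction))
})

test_that("raising the threshold never creates new substrates", {
  fam <- makeNmdBoundaryFamily(c(40, 55, 56, 70, 90), seed = 3)
  for (loc in fam) {
    rec <- applyEvent(loc$genome, loc$model, skipEvent(2))
    sc <- scanOrf(rec@mature)
    prev <- TRUE
    for (thr in c(30L, 55L, 80L, 120L)) {
      v <- classifyNmd(rec@mature, sc$stopPos, NA,
                       nmdRuleConfig(thresholdNt = thr))
      expect_true(prev || !v@nmdSubstrate)  # monotone non-increasing
      prev <- v@nmdSubstrate
    }
  }
})

test_that("designReport rows agree with the constituent operations", {
  loc <- makeLocus(locusSpec(5, c(120, 100, 90, 110, 140),
                             c(150, 120, 100, 130), seed = 1))
  rep <- designReport(loc$genome, loc$model, maxRun = 2)
  expect_identical(nrow(rep), 5L)
  for (i in seq_len(nrow(rep))) {
    idx <- as.integer(strsplit(rep$exons[i], "+", fixed = TRUE)[[1]])
    rec <- applyEvent(loc$genome, loc$model, skipEvent(idx))
    expect_identical(rep$frameshift[i], frameDisruption(rec))
    sc <- scanOrf(rec@mature)
    expect_identical(rep$ptc_pos[i], sc$stopPos)
    j <- junctions(rec@mature)
    expect_identical(rep$distance_nt[i], j[length(j)] - sc$stopPos)
  }
  # in-frame skip whose stop maps back to the reference stop: no substrate
  inframe <- rep[rep$frameshift == FALSE, ]
  expect_true(all(!inframe$nmd_substrate))

  twoExon <- transcriptModel("t2", "g", names(loc$genome), "+",
                             IRanges::IRanges(c(1, 400), c(100, 500)),
                             10, 450)
  expect_warning(repEmpty <- designReport(loc$genome, twoExon))
  expect_identical(nrow(repEmpty), 0L)
})
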