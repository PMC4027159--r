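test_that("default tiling walks an 18-mer every 3 nt across exon and splice sites", {
  loc <- makeLocus(locusSpec(3, c(100, 60, 120), c(150, 150), seed = 2))
  cand <- tileAso(loc$genome, loc$model, 2)
  # window 60 + 2*15 = 90 nt -> floor((90-18)/3)+1 = 25 candidates
  expect_length(cand, 25L)
  expect_true(all(nchar(cand$asoSequence) == 18L))
  expect_identical(unique(diff(BiocGenerics::start(cand))), 3L)
  # first and last candidates span the acceptor (3'ss) and donor (5'ss)
  expect_true(cand$overlaps3ss[1])
  expect_true(cand$overlaps5ss[length(cand)])
  expect_false(any(cand$overlaps5ss[1:5]))
  # every ASO is the reverse complement of its sense window
  g <- as.character(loc$genome[[1]])
  sense <- substring(g, BiocGenerics::start(cand), BiocGenerics::end(cand))
  expect_identical(cand$asoSequence, vapply(sense, revComp, character(1),
                                            USE.NAMES = FALSE))
  expect_identical(unique(as.character(BiocGenerics::strand(cand))), "-")
})

test_that("tiling is strand-aware: minus-strand ASOs target the same mRNA", {
  specP <- locusSpec(3, c(100, 60, 120), c(150, 150), seed = 2,
                     strand = "+")
  specM <- specP; specM$strand <- "-"
  locP <- makeLocus(specP); locM <- makeLocus(specM)
  cp <- tileAso(locP$genome, locP$model, 2)
  cm <- tileAso(locM$genome, locM$model, 2)
  expect_identical(cp$asoSequence, cm$asoSequence)
  expect_identical(cp$overlaps5ss, cm$overlaps5ss)
  expect_identical(cp$overlaps3ss, cm$overlaps3ss)
  expect_identical(cp$exonOverlapNt, cm$exonOverlapNt)
  expect_identical(unique(as.character(BiocGenerics::strand(cm))), "+")
  # minus-strand ASO sequences are plain genomic-forward substrings
  g <- as.character(locM$genome[[1]])
  expect_identical(cm$asoSequence[1],
                   substring(g, BiocGenerics::start(cm)[1],
                             BiocGenerics::end(cm)[1]))
})

test_that("candidate count matches exhaustive window enumeration", {
  set.seed(7)
  for (i in 1:40) {
    exLen <- sample(20:120, 1)
    L <- sample(12:25, 1)
    cfg <- tilingConfig(asoLength = L, step = sample(1:min(6, L), 1),
                        flank = sample(0:(L - 1), 1))
    loc <- makeLocus(locusSpec(3, c(80, exLen, 90), c(60, 60), seed = i))
    cand <- tileAso(loc$genome, loc$model, 2, cfg)
    expect_length(cand,
                  oracleTileCount(exLen + 2 * cfg$flank, L, cfg$step))
    expect_true(all(cand$exonOverlapNt >= L - cfg$flank))
  }
})

test_that("degenerate window: flank 0 and exon length == ASO length", {
  loc <- makeLocus(locusSpec(3, c(100, 18, 120), c(150, 150), seed = 3))
  cand <- tileAso(loc$genome, loc$model, 2,
                  tilingConfig(asoLength = 18, step = 3, flank = 0))
  expect_length(cand, 1L)
  expect_identical(cand$exonOverlapNt, 18L)
  expect_false(cand$overlaps5ss)
  expect_false(cand$overlaps3ss)
})

test_that("a window that leaves the sequence is an explicit error", {
  loc <- makeLocus(locusSpec(3, c(10, 60, 120), c(5, 150), seed = 4))
  expect_error(tileAso(loc$genome, loc$model, 1), "no silent clipping")
})

test_that("chemistry profiles fill per-position sugars", {
  expect_identical(chemistryProfile("uniform_moe", 18)$sugars,
                   rep("MOE", 18))
  gap <- chemistryProfile("gapmer_5_10_5", 20)$sugars
  expect_identical(gap, c(rep("MOE", 5), rep("DNA", 10), rep("MOE", 5)))
  expect_error(chemistryProfile("gapmer_5_10_5", 18), "length 20")
  expect_identical(chemistryProfile("uniform_moe", 18)$backbone,
                   rep("PS", 17))
  expect_error(chemistryProfile("custom", 4, sugars = c("MOE", "XXX",
                                                        "DNA", "DNA")),
               "unknown sugar")

  loc <- makeLocus(locusSpec(3, c(100, 60, 120), c(150, 150), seed = 2))
  cand <- applyChemistry(tileAso(loc$genome, loc$model, 2), "uniform_moe")
  expect_identical(unique(cand$sugars),
                   paste(rep("MOE", 18), collapse = ","))
  g20 <- applyChemistry(
    tileAso(loc$genome, loc$model, 2, tilingConfig(asoLength = 20)),
    "gapmer_5_10_5")
  expect_identical(unique(g20$chemistry), "gapmer_5_10_5")
})

test_that("candidate writers follow BED/FASTA conventions and TSV round-trips", {
  loc <- makeLocus(locusSpec(3, c(100, 60, 120), c(150, 150), seed = 2))
  cand <- applyChemistry(tileAso(loc$genome, loc$model, 2), "uniform_moe")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeCandidates(cand, bed, "bed")
  f <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_identical(as.integer(f[2]), BiocGenerics::start(cand)[1] - 1L)
  expect_identical(as.integer(f[3]), BiocGenerics::end(cand)[1])
  expect_identical(f[6], "-")  # ASO strand is antisense on a + transcript

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeCandidates(cand, tsv, "tsv")
  expect_identical(as.data.frame(readCandidates(tsv)),
                   as.data.frame(cand))
  # determinism: identical inputs give byte-identical TSV
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeCandidates(applyChemistry(tileAso(loc$genome, loc$model, 2),
                                 "uniform_moe"), tsv2, "tsv")
  expect_identical(readLines(tsv), readLines(tsv2))

  fa <- withr::local_tempfile(fileext = ".fa")
  writeCandidates(cand, fa, "fasta")
  seqs <- readGenome(fa)
  g <- as.character(loc$genome[[1]])
  expect_identical(as.character(seqs[[1]]),
                   revComp(substring(g, BiocGenerics::start(cand)[1],
                                     BiocGenerics::end(cand)[1])))
  expect_error(writeCandidates(cand, tsv, "xlsx"))
})
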