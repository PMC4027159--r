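test_that("readGenome normalizes case, line wraps, and RNA bases", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt"), fa)
  g <- readGenome(fa)
  expect_identical(names(g), "x")
  expect_identical(as.character(g[[1]]), "ACGT")

  writeLines(c(">x", "ACG", "T"), fa)
  expect_identical(as.character(readGenome(fa)[[1]]), "ACGT")

  writeLines(c(">rna", "acgu"), fa)
  expect_identical(as.character(readGenome(fa)[[1]]), "ACGT")
})

test_that("readGenome rejects bad records by name", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACJT"), fa)
  expect_error(readGenome(fa), "'x'")
  writeLines(c(">empty", "", ">y", "ACGT"), fa)
  expect_error(readGenome(fa), "empty")
})

test_that("revComp matches definition and is an involution", {
  expect_identical(revComp("ACGT"), "ACGT")
  expect_identical(revComp("AATTCC"), "GGAATT")
  expect_identical(revComp("AN"), "NT")
  expect_error(revComp("AXGT"), "outside")
  set.seed(42)
  for (i in 1:25) {
    x <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:60, 1),
                      replace = TRUE), collapse = "")
    expect_identical(revComp(revComp(x)), x)
  }
})

test_that("transcript model validity catches structural errors", {
  expect_error(
    transcriptModel("t", "g", "chr", "+",
                    IRanges::IRanges(c(11, 13), c(20, 21)), 11, 21),
    "overlapping")
  expect_error(
    transcriptModel("t", "g", "chr", "+",
                    IRanges::IRanges(c(1, 10), c(3, 12)), 5, 12),
    "cdsStart")
})

test_that("annotation IO preserves 1-based inclusive GFF3 coordinates", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tgene\t11\t40\t.\t+\t.\tID=gene:g1",
    "chr\tsrc\tmRNA\t11\t40\t.\t+\t.\tID=transcript:t1;Parent=gene:g1",
    "chr\tsrc\texon\t11\t16\t.\t+\t.\tParent=transcript:t1",
    "chr\tsrc\texon\t30\t40\t.\t+\t.\tParent=transcript:t1",
    "chr\tsrc\tCDS\t12\t16\t.\t+\t.\tParent=transcript:t1",
    "chr\tsrc\tCDS\t30\t38\t.\t+\t.\tParent=transcript:t1"), gff)
  m <- readAnnotation(gff)[["t1"]]
  expect_identical(BiocGenerics::start(exons(m)), c(11L, 30L))
  expect_identical(BiocGenerics::end(exons(m)), c(16L, 40L))
  expect_identical(cdsStart(m), 12L)
  expect_identical(cdsEnd(m), 38L)
  expect_identical(geneId(m), "g1")
})

test_that("overlapping exons in annotation are a validation error", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tmRNA\t11\t20\t.\t+\t.\tID=transcript:t1;Parent=gene:g1",
    "chr\tsrc\texon\t11\t16\t.\t+\t.\tParent=transcript:t1",
    "chr\tsrc\texon\t13\t20\t.\t+\t.\tParent=transcript:t1"), gff)
  expect_error(readAnnotation(gff), "overlapping")
})

test_that("a generated 5-exon locus round-trips through GFF3", {
  loc <- makeLocus(locusSpec(5, c(120, 100, 90, 110, 140),
                             c(150, 120, 100, 130), seed = 11))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotation(list(loc$model), gff)
  m2 <- readAnnotation(gff)[[transcriptId(loc$model)]]
  expect_identical(as.data.frame(exons(m2)), as.data.frame(exons(loc$model)))
  expect_identical(cdsStart(m2), cdsStart(loc$model))
  expect_identical(cdsEnd(m2), cdsEnd(loc$model))
  # and against the generator's own truth table
  tt <- loc$truth$exonTable
  expect_identical(BiocGenerics::start(exons(m2)), tt$genomicStart)
  expect_identical(BiocGenerics::end(exons(m2)), tt$genomicEnd)
})

test_that("splicing concatenates exons and recomputes junctions", {
  toy <- toyLocus()
  mat <- spliceTranscript(toy$genome, toy$plus)
  expect_identical(as.character(mrnaSequence(mat)), "AAATTT")
  expect_identical(junctions(mat), 4L)

  matM <- spliceTranscript(toy$genome, toy$minus)
  expect_identical(as.character(mrnaSequence(matM)),
                   oracleSplice(toy$genome, c(1, 10), c(3, 12), "-"))

  bad <- transcriptModel("t", "g", "chr", "+",
                         IRanges::IRanges(c(1, 14), c(3, 20)), 1, 20)
  expect_error(spliceTranscript(toy$genome, bad), "out of bounds")
})

test_that("splice length conservation and strand symmetry hold on random loci", {
  for (seed in 1:8) {
    spec <- randomLocusSpec(seed)
    loc <- makeLocus(spec)
    mat <- spliceTranscript(loc$genome, loc$model)
    expect_identical(length(mrnaSequence(mat)),
                     sum(BiocGenerics::width(exons(loc$model))))
    # the minus-strand mirror locus yields the identical mRNA
    specM <- spec; specM$strand <- if (spec$strand == "+") "-" else "+"
    locM <- makeLocus(specM)
    matM <- spliceTranscript(locM$genome, locM$model)
    expect_identical(as.character(mrnaSequence(matM)),
                     as.character(mrnaSequence(mat)))
    expect_identical(junctions(matM), junctions(mat))
  }
})

test_that("genomic/mRNA coordinate maps are inverse bijections on exons", {
  toy <- toyLocus()
  expect_identical(genomicToMrna(toy$plus, 10L), 4L)
  expect_true(is.na(genomicToMrna(toy$plus, 6L)))
  expect_error(genomicToMrna(toy$plus, 14L), "span")
  for (seed in c(3, 4)) {
    loc <- makeLocus(randomLocusSpec(seed))
    ex <- exons(loc$model)
    gpos <- unlist(Map(seq, BiocGenerics::start(ex), BiocGenerics::end(ex)))
    m <- genomicToMrna(loc$model, gpos)
    expect_false(anyNA(m))
    expect_identical(sort(m), seq_along(m))  # bijective onto 1..L
    expect_identical(mrnaToGenomic(loc$model, m), as.integer(gpos))
    # intronic positions report as NA
    introns <- setdiff(seq(min(gpos), max(gpos)), gpos)
    if (length(introns))
      expect_true(all(is.na(genomicToMrna(loc$model, introns))))
  }
})
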