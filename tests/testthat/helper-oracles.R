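# independent brute-force oracles used to cross-check the implementation

# first in-frame stop by literal codon-by-codon walk with substr
oracleFirstStop <- function(seq, cdsStart) {
  p <- as.integer(cdsStart)
  while (p + 2L <= nchar(seq)) {
    if (substr(seq, p, p + 2L) %in% c("TAA", "TAG", "TGA")) return(p)
    p <- p + 3L
  }
  NA_integer_
}

# naive double-loop PWM scan
oracleScanPwm <- function(seq, weights, threshold) {
  w <- ncol(weights)
  hits <- data.frame(start = integer(), score = numeric())
  for (s in seq_len(nchar(seq) - w + 1)) {
    sc <- 0
    ok <- TRUE
    for (i in seq_len(w)) {
      b <- substr(seq, s + i - 1, s + i - 1)
      if (!b %in% rownames(weights)) { ok <- FALSE; break }
      sc <- sc + weights[b, i]
    }
    if (ok && sc >= threshold)
      hits <- rbind(hits, data.frame(start = s, score = sc))
  }
  hits
}

# exhaustive tiling-window enumeration
oracleTileCount <- function(windowLen, asoLength, step) {
  n <- 0L
  s <- 1L
  while (s + asoLength - 1L <= windowLen) {
    n <- n + 1L
    s <- s + step
  }
  n
}

# splice by per-exon extraction; for minus strand, revcomp each exon and
# reverse the exon order (independent of the whole-transcript revcomp path)
oracleSplice <- function(genomeSeq, starts, ends, strand) {
  pieces <- substring(genomeSeq, starts, ends)
  if (strand == "-") {
    pieces <- rev(vapply(pieces, revComp, character(1)))
  }
  paste(pieces, collapse = "")
}

# coding nucleotides removed by dropping a set of exons, from interval
# arithmetic on the genomic CDS range
oracleRemovedCoding <- function(model, dropIdx) {
  ex <- exons(model)
  lo <- cdsStart(model); hi <- cdsEnd(model)
  ov <- pmax(0L, pmin(BiocGenerics::end(ex), hi) -
               pmax(BiocGenerics::start(ex), lo) + 1L)
  sum(ov[dropIdx])
}

# toy two-exon locus used across files
toyLocus <- function() {
  list(genome = "AAACCCGGGTTTAAA",
       plus = transcriptModel("toy", "toyg", "chr", "+",
                              IRanges::IRanges(c(1, 10), c(3, 12)), 1, 12),
       minus = transcriptModel("toym", "toyg", "chr", "-",
                               IRanges::IRanges(c(1, 10), c(3, 12)), 1, 12))
}

randomLocusSpec <- function(seed) {
  set.seed(seed)
  nEx <- sample(4:7, 1)
  locusSpec(nEx,
            exonLengths = sample(30:150, nEx, replace = TRUE),
            intronLengths = sample(60:200, nEx - 1, replace = TRUE),
            cdsOffset = sample(3:12, 1),
            seed = seed,
            strand = sample(c("+", "-"), 1))
}
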