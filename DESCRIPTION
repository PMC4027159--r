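Package: skipNMD
Title: Design of Exon-Skipping Antisense Oligonucleotides that Trigger
    Nonsense-Mediated Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the rational design of steric-blocking antisense
    oligonucleotides (ASOs) that induce exon skipping and route the
    mis-spliced transcript to nonsense-mediated mRNA decay (NMD). Builds
    transcript models from FASTA and GFF3/GTF input, simulates exon
    skipping, cryptic splice-site use and intron retention, scans the
    resulting open reading frames for premature termination codons and
    classifies NMD substrates by the 55-nt last-junction rule, tiles ASO
    candidates across target exons and their splice sites with
    per-position chemistry profiles, scans exons for exonic splicing
    enhancer motifs with user-supplied position weight matrices, and
    implements the downstream assay arithmetic: molar-corrected percent
    exon skipping from gel densitometry, relative-standard-curve qPCR
    quantification, and 5' RACE cleavage-site mapping. A synthetic locus
    generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
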