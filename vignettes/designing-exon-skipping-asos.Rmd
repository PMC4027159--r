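---
title: "Designing exon-skipping antisense oligonucleotides that trigger NMD"
author: "skipNMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing exon-skipping antisense oligonucleotides that trigger NMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipNMD)
```

## The design problem

Most ASOs that lower a target mRNA do so enzymatically, by recruiting
RNase H (DNA-gap ASOs) or RISC (siRNA). Steric-blocking chemistries such
as uniform 2′-MOE support neither enzyme, but they can redirect splicing.
skipNMD implements the in-silico side of a rational design strategy that
turns a splice-switching steric blocker into a knockdown reagent: choose
a constitutive exon whose loss shifts the reading frame, tile ASOs across
that exon and its splice sites, and let the cell's own
nonsense-mediated decay (NMD) machinery destroy the frameshifted,
premature-termination-codon (PTC)-containing product.

The package covers five stages, each usable on its own:

1. **Transcript models** — FASTA + GFF3/GTF in, spliced mature mRNA and
   coordinate maps out.
2. **Isoform simulation** — exon skipping (single or contiguous
   multi-exon), cryptic donor/acceptor use, and intron retention; ORF
   re-scan and NMD classification of each product.
3. **ASO tiling** — candidate walks across the target exon with
   per-position chemistry profiles.
4. **ESE scanning** — additive PWM scans for exonic splicing enhancer
   motifs under each candidate.
5. **Assay arithmetic** — molar-corrected percent skipping from gel
   densitometry, relative-standard-curve qPCR, and 5′ RACE cleavage-site
   mapping.

## The NMD rule and its parameters

A spliced mRNA whose termination codon sits well upstream of its final
exon–exon junction retains an exon junction complex downstream of the
terminating ribosome, which licenses decay. The classifier uses the
standard distance formulation: an isoform is a predicted NMD substrate
when its stop codon is *premature* (structurally different from the
isoform-mapped reference stop) **and** lies strictly more than
`thresholdNt` nucleotides upstream of the last exon–exon junction.

Two conventions needed fixing and travel with every verdict in
`nmdRuleConfig()`:

* **Threshold, 55 nt, strict.** The rule is stated as "greater than
  55 nt", so a distance of exactly 55 is *not* a substrate and 56 is.
  `thresholdNt` is a tunable integer, default 55.
* **Distance anchor.** Statements of the 50–55 nt rule rarely say
  whether the distance is measured to the first or last base of the stop
  codon. We anchor at the first (5′-most) nucleotide of the stop and use
  that consistently; with a 3-nt codon the alternative would shift every
  distance by 2 nt, which matters only within 2 nt of the boundary.

Other structural decisions:

* `isPremature` is structural (stop position differs from where the
  reference stop maps on the isoform), not protein-length based, so an
  in-frame skip whose stop is unchanged is never called premature.
* Codons created across a novel junction are read like any other: the
  scan runs on the final isoform sequence with no special casing.
* Intron retention removes the retained intron's junction from the
  junction chain before the rule is applied — that junction no longer
  exists on the mature species.
* Events that remove the start codon yield a `startLost` record that is
  excluded from frame and NMD classification instead of guessing at
  downstream reinitiation.
* Single-exon (junction-less) isoforms are never substrates; their
  distance is reported as `NA`.

## Tiling geometry and chemistry

The tiling defaults reproduce an unbiased splice-site-inclusive screen:
18-mer candidates spaced every 3 nt. The window is
`[exon start − flank, exon end + flank]` with `flank = 15` by default.
The intronic extent of such screens is rarely stated numerically; 15 nt
with an 18-mer guarantees every junction-spanning candidate keeps at
least 3 exonic nucleotides, matching the 3-nt step granularity, and the
parameter is an explicit, overridable part of `tilingConfig()`. The
constraint `flank < asoLength` keeps every candidate overlapping the
exon.

Candidates are emitted 5′→3′ along the *transcript*, so minus-strand
genes tile from the genomic right; the ASO sequence is always the
reverse complement of the sense-strand target window. No thermodynamic
or off-target filtering is applied — the screen is deliberately
unbiased, and such filters belong downstream.

Chemistry profiles are per-position sugar assignments with a full
phosphorothioate backbone: `uniform_moe` (the steric blocker the design
strategy needs), `gapmer_5_10_5` (five 2′-MOE wing positions around a
ten-deoxy RNase H-competent gap; requires a 20-mer), `uniform_2ome`,
`cet_mixmer` (alternating cEt/DNA, this package's mixmer convention —
published mixmers vary and a `custom` profile accepts any pattern).

## ESE scanning

Splice-blocking ASOs that sit mid-exon often act by occluding exonic
splicing enhancers bound by SR proteins. `scanPwm()` is a plain additive
PWM scan: window score = sum of per-position weights, hits at score ≥
threshold. No background model is imposed; if log-odds scoring is wanted
it belongs in the matrix file. Published SR-protein matrices (e.g. the
ESEfinder set) are *not* bundled — they are not ours to reprint — so
matrices are user inputs, and the fixture generator ships clearly
labeled synthetic example matrices instead. Scanning is sense-strand
only, since enhancers act on the pre-mRNA sense sequence.

## Assay arithmetic

**Percent skipping.** Gel densitometry reports
`100 · exclusion / (inclusion + exclusion)` after dividing each band by
its product length in bp. The division is the ethidium-bromide
correction: EtBr fluorescence scales with DNA mass, molarity with
mass/length. The algebra of the correction is rarely written out; this
is the standard interpretation and `bandPercentages()` generalizes it to
lanes with three or more bands (double-skip products), reducing to the
two-band formula.

**qPCR.** `fitStandardCurve()` is an ordinary least-squares fit of
`ct ~ log10(quantity)`; `quantifyCt()` inverts it and divides by a
single normalizer scalar (a total-RNA proxy such as a RiboGreen
measurement). No efficiency correction beyond the fitted slope, no
ΔΔCt.

**5′ RACE.** Clones are mapped by exact match of their first
`minAnchor` (default 15, minimum 10) nucleotides: a unique match calls a
cleavage site at the clone's 5′ end, zero matches leave it unmapped,
several leave it ambiguous. Exact anchoring rather than alignment is
appropriate for Sanger-confirmed clones; mismatch-tolerant mapping is
out of scope. Counts always conserve:
mapped + unmapped + ambiguous + skipped = total.

## What the synthetic loci emulate — and what they do not

`makeLocus()` realizes a declared exon/intron geometry with random
sequence under three hard guarantees: the reference ORF contains no
premature in-frame stop (coding sequence is built codon-by-codon with
stops rejected), the reference stop lies in the last exon, and introns
carry canonical GT...AG ends. The per-exon truth table (coding content,
cumulative frame phase) makes every downstream classification checkable
by construction.

`makeNmdBoundaryFamily()` isolates the threshold variable: for each
requested distance `d` it builds a 4-exon locus (exons 120/100/~90/~150
nt) where skipping the 100-nt exon 2 shifts the frame and the first new
stop lands exactly `d` nt upstream of the skipped isoform's last
junction. The third exon's length absorbs the ±2 nt needed to keep the
stop frame-aligned, so only the distance varies. Because exon 3 is read
in two different frames (reference and shifted), its sequence must be
stop-free in both; the generator constructs the shifted frame exactly
and rejection-samples the rest, then verifies each member by actually
running `applyEvent()`/`scanOrf()`/the junction arithmetic before
returning it.

These fixtures are *not* biological sequence simulators: no codon-usage
realism, no splice-site strength model, no ESE/ESS landscape, uniform
base composition. Tests passing on them demonstrate that the coordinate
arithmetic, frame logic and classification rules are exact — not that
real exons will skip when tiled, which is an experimental question.

Generation is bit-for-bit reproducible under a seed; written fixture
files record the seed in their headers.

## Numerical and degenerate-input choices

* Internal coordinates are 1-based closed `IRanges`, the native
  Bioconductor convention, converted at every file boundary (GFF3/GTF
  1-based inclusive; BED 0-based half-open). All overlap arithmetic is
  closed-interval; the documented boundary semantics ("a hit touching a
  candidate's edge does not intersect") are preserved exactly.
* Minus-strand transcripts are fully normalized at splice time —
  downstream logic sees only 5′→3′ mRNA coordinates, one code path.
* `N` bases are legal in genomes; PWM windows containing `N` are
  skipped with a warning count, and ORF scans through `N` return a
  flagged result rather than failing.
* A tiling window that would leave the sequence is an error, never a
  silent clip.
* Both-bands-zero densitometry, single-quantity standard curves,
  zero-slope inversion, sub-anchor RACE clones: all explicit errors or
  warnings, never NaN propagation.

## Problem sizes used in the checks

The shipped test suite exercises the oracle comparisons at 1,000 seeded
random cases per primitive (ORF scan vs a literal codon walk, PWM scan
vs a naive double loop, tiling counts vs exhaustive enumeration), the
frameshift law over all enumerated skips on 200 random loci, and the
NMD boundary family at distances 50–60 nt. These sizes give exhaustive
coverage of the discrete structures involved (frame phases, boundary
offsets) while keeping a full run around two minutes.

## Known limitations

* NMD is modeled by the distance rule alone — no EJC deposition model,
  no UPF1/SMG6 kinetics, no tissue-specific NMD efficiency, and no
  prediction of *skipping efficiency* from ASO sequence or
  thermodynamics.
* The nuclear arm of decay seen for some steric blockers (intron
  retention coupled to chromatin-associated turnover) is represented
  structurally (retention isoforms) but not kinetically.
* Cryptic-site events model a single activated site per event.
* RACE mapping is exact-match; clones from a transcript with repeated
  15-mers at the cleavage point will be called ambiguous.
* Real isoform choice (which annotated transcript of a gene to target)
  is reduced to "longest CDS" when a gene rather than a transcript is
  named; the package never hardcodes real gene structures.
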