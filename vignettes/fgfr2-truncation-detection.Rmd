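---
title: "Detecting FGFR2 exon-18-truncating alterations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting FGFR2 exon-18-truncating alterations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfr2trunc)
```

## The biological model

FGFR2's terminal exon (E18) encodes the receptor's C-terminal tail,
which carries negative-regulatory elements. Alterations that remove
E18 while preserving exons 1–17 produce a truncated receptor
(FGFR2ΔE18) with oncogenic activity. Four DNA mechanisms converge on
the same protein product:

1. **Rearrangements with a breakpoint in intron 17 or exon 18** —
   classical in-frame fusions, but also fusions with unpredictable
   frame, junctions into intergenic space, out-of-strand junctions,
   and intragenic deletions. All sever E18 from the upstream kinase
   domain.
2. **E1–E17 partial amplification** — a copy-number gain whose distal
   boundary falls inside intron 17, amplifying a truncated template.
3. **E18 splice-acceptor mutations** — loss of the acceptor forces
   splicing into alternative or cryptic terminal exons.
4. **Proximal C-terminal truncating mutations** — nonsense/frameshift
   changes in residues E768–Y783; truncations in the distal tail
   (P784–T821) retain most regulatory elements and are recorded but
   never counted as truncating.

RNA-level evidence (partner/intergenic junction usage from the E17
donor, usage of the dysfunctional alternative last exons E18-C3/C4,
and loss of E18 expression relative to E1–E17) corroborates the DNA
calls; the integrator treats DNA and RNA as independent evidence lines
and assigns categories from DNA evidence, recording RNA flags as
annotations.

## Reading-frame arithmetic

Exon phases are computed from cumulative coding length: exon $k$
starts at phase $\phi_k = L_{<k} \bmod 3$ and ends at phase
$(L_{\le k}) \bmod 3$, where $L$ counts coding bases. A junction with
both breakpoints in introns is **in-frame** when the end phase of the
upstream exon equals the start phase of the downstream exon. A
junction with both breakpoints in exons is in-frame when the phases at
the exact break offsets match; a mixed exon/intron junction disrupts a
splice boundary on one side only and is always frame-unknown. This
splice-phase definition is the standard fusion-frame criterion; we do
not additionally require each flanking exon to be codon-complete. The
stricter reading ("complete reading frame" as codon-complete flanking
exons) is available via `classify_re(..., frame_rule =
"codon_complete")`, because the phrase is genuinely ambiguous; the
default reproduces canonical I17 fusions as in-frame, which the
stricter reading does not (exon 17 ends at phase 1).

The test suite and the acceptance script verify the phase arithmetic
against an independent oracle that materializes the fused coding
sequence with a random partner CDS and checks by translation
(Biostrings) that the partner's peptide tail survives in the fusion
product.

## Rule order and the allele-frequency threshold

The six rearrangement types are evaluated in a fixed order:
UNRESOLVED (upstream side antisense-supported, or a single breakend)
→ INTERNAL (both ends inside FGFR2) → INTERGENIC_SPACE →
OUT_OF_STRAND → frame evaluation (IN_FRAME_FUSION / FRAME_UNKNOWN).
The source material lists the types without an explicit precedence;
this order resolves every junction to exactly one type and puts the
unconditional diagnoses before the frame test.

The rearrangement allele frequency is junction ploidy divided by the
total gene copy number at the upstream breakend, clamped to [0, 1].
The exact quantity used as "ploidy" by the upstream caller is not
specified in the source material; the quotient-with-clamp is this
package's concrete definition and is recorded in the call object. A
sample is E18-truncated at DNA level when any I17/E18 rearrangement
that is not UNRESOLVED has allele frequency strictly greater than
0.15. With several rearrangements per sample, each gets its own
frequency and the sample-level call is the disjunction.

## Amplification calling

Four rule sets share one surface but differ in scale and thresholds,
following the printed inequalities exactly:

| rule set | scale | amplification | partial E1–E17 |
|---|---|---|---|
| WGS | absolute CN | CN > 5 (strict) | I17 segment break, CN(E1–E17) > 5, difference > 2 |
| TCGA | log2(CN/2) | value > 0.3 | I17 break, value > 0.3, difference > 0.3 |
| CCLE | log2(CN/2) | value ≥ 2 (inclusive) | — |
| PANEL | per-exon targets | ≥ 80% of targets ≥ 4 + median ploidy | ≥ 80% of E1–E17 targets amplified, E18 below threshold |

Block copy numbers are length-weighted means of the segments
overlapping the E1–E17 span and the E18 exon; the summary statistic is
not stated in the source material and the length-weighted mean is the
natural choice for segmented data. Segment-break detection in intron
17 tolerates ±1 bp, guarding against coordinate-dialect off-by-ones.
The panel rule's "differential gain" margin for E18 is not quantified
in the source material; the implementation requires E18 below the
amplification threshold while ≥ 80% of E1–E17 targets pass, with the
margin exposed as `e18_margin`.

## Mutation and RNA evidence parameters

* Hotspot residues are configuration data
  (`default_hotspots()`): FGFR2 S252/C382/N549/K659, FGFR3
  R248/S249/Y373/K650. Classification is by residue position;
  one-letter, three-letter and triplet input formats are equivalent.
* The E18 splice-acceptor window is the 2 intronic bases preceding E18
  plus its first exonic base (`splice_window_intronic = 2`); only
  "splice-acceptor-site mutations" is stated, so the window is
  configurable. Whether I17 splice-donor variants were counted by the
  diagnostic pipeline is unknown; we do not count them by default.
* Frameshifts are located at the first altered residue.
* RNA truncation evidence defaults to rearrangement acceptors only
  (partner genes, intergenic pseudo-exons, transposon acceptors),
  matching the quoted junction-frequency rule; E18-C3/C4 can be added
  via `evidence_classes`. E18-C2 is treated as full-length-like and
  never counts, since C2 retains most regulatory function.
* Undefined usage (zero E17 junction reads) propagates as `NA`, never
  as 0.
* Composite FGFR expression operates on linear-scale values with a
  pseudocount (default 0.01) replacing zeros before the geometric
  mean; the scale of the "> 3" threshold is not stated in the source
  material, so both the score scale and the threshold are parameters.

## Co-driver statistics

The proportion Z-test compares the alteration proportion of a driver
gene in the focal FGFR2 category against the pooled other two altered
categories (default), with a one-tailed upper p value from the pooled
standard normal statistic. Whether the original contrast included
wild-type samples is not stated; `mode = "vs_all_others"` provides the
alternative. Fisher exact tests compare each category against
wild-type samples with the two-sided p defined by point-probability
summation (the convention of `stats::fisher.test`, reproduced here via
`dhyper` and verified against exhaustive enumeration); the reported
odds ratio is the cross-product estimate with Haldane–Anscombe +0.5
correction applied to all cells only when a cell is zero, and the 95%
interval is the Woolf normal approximation on the log odds ratio
— matching a log2-OR ± CI presentation. Benjamini–Hochberg correction
is applied within each category's gene list (per-panel correction).
Note that BH is not idempotent: re-adjusting q values inflates them,
so q values are computed exactly once per family.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` generates, from one mandatory seed, a toy
annotation (an 18-exon FGFR2 with a 5-kb intron 17; partners with
compatible and incompatible phases, a minus-strand partner, a
non-coding gene), BEDPE breakpoint pairs placed per planted
rearrangement type, copy-number segments and per-exon panel targets,
MAF-like small variants, multinomial junction tables, exon expression
matrices with designated normals, and a binary driver matrix drawn
from a logistic model with planted per-category log odds ratios.

Chosen study conditions (fixed once, stated here rather than tuned):

* The three altered categories keep their printed pan-cancer relative
  sizes (1367 : 838 : 978) but are scaled to half the cohort, because
  at the printed ~1% incidence a 1,000-sample cohort would carry too
  few altered samples to exercise every branch of the classifier.
* The mechanism mixture inside the truncated class follows the printed
  subgroup counts (757/82/291/88/29/21/59/73).
* Allele frequencies are drawn uniformly away from the 0.15 boundary
  (passing from U(0.20, 1.0), failing from U(0.02, 0.12), 10%
  failing), so planted truth is unambiguous; junction ploidy is
  derived from the emitted (noisy) gene copy number so the planted
  frequency is recovered exactly.
* Copy-number noise is Gaussian (sd 0.1) truncated at 0; planted
  levels (2 / 8 / 8-vs-3) sit several standard deviations from every
  threshold.
* Junction counts are multinomial at depth 2,000 (10,000 in the
  convergence tests); partner usage is 0.6 for passing and 0.08 for
  failing rearrangements.
* All randomness flows from the root seed through fixed per-block
  sub-seeds (`seed * 1009 + k * 7919 mod 2^31`), so adding a generator
  never perturbs existing streams and a seed reproduces the bundle
  byte-exactly.

The generator works at the call/count level. It does not emulate read
alignment artefacts, segmentation error, subclonal structure, multiple
isoforms, overlapping genes, or derivative-chromosome complexity —
passing planted-truth recovery therefore demonstrates correctness of
the classification logic, not robustness to upstream caller noise.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GTF I/O converts to and
  from 1-based inclusive, BEDPE stays 0-based. Exon/intron indices are
  1-based in transcript order, so "I17" is the intron between exons 17
  and 18.
* The canonical transcript is the one with the longest CDS, ties
  broken lexicographically: determinism matters more than the specific
  rule, which the source material does not state.
* Printed percentages use half-up rounding at the printed precision
  (2 decimals for incidences, 1 for class fractions), verified against
  all printed values.
* Degenerate inputs fail loudly: all-zero ligation scores, non-positive
  gene copy number, zero-total junction tables (NA, not 0), cohorts of
  fewer than 3 samples for outlier Z-scores (constant vectors warn and
  flag nothing), empty 2x2 margins, and control arms with non-positive
  volume change (undefined ratio marker).
* Sliding-window densities use centred half-open windows so that
  windows spaced one window apart tile the genome and conserve counts.

## Problem sizes

The default test-suite and acceptance problem sizes are 1,000-sample
cohorts for planted-truth recovery, 1,000 random gene pairs for the
frame oracle, exhaustive enumeration of all 2x2 tables with n ≤ 60
for the Fisher check, and 200 replicates of 2,000-sample cohorts for
the calibration of the co-driver statistics. These sizes give binomial
standard errors small enough to make the calibration checks
informative while keeping a full run in the order of a minute.

## Known limitations

* One canonical transcript per gene; alternative isoform numbering
  (e.g. the IIIb/IIIc distinction) is not modelled, and fixtures use a
  generic 18-exon structure.
* Frame prediction is length-based; no genome sequence is consulted,
  so fusions that create stop codons at the junction are still called
  in-frame if phases match.
* Complex rearrangements are classified per junction; no
  derivative-chromosome reconstruction.
* The pipeline consumes caller output (breakpoints, segments, protein
  changes, junction counts); it neither aligns reads nor calls
  variants.
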