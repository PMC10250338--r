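---
title: "Methods: models, parameters and design choices in minicircler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in minicircler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicircler)
```

## The biological model

Some organelle genomes are *multipartite*: instead of one chromosome, the
gene set is scattered over many small circular DNA molecules
("minicircles"), each a few kb in size. In the systems this package
targets — minicircular mitochondrial genomes of unicellular red algae —
every minicircle has the same anatomy:

* a **cassette**: one CDS plus a short gene-specific non-coding flank;
* a **constant region**: a non-coding arc shared near-identically among
  many minicircles of the same species, typically containing **repeat
  regions** whose tandem unit count varies from circle to circle. A species
  can carry more than one constant-region type; circles sharing a type form
  a **constant group**.

Long reads from such genomes have a characteristic signature: read lengths
peak at the originating circle's length, and a small fraction of reads are
**concatemers** containing several minicircle units. Concatemers of one
circle (**homo**) are explained by rolling-circle replication; concatemers
joining *different* genes (**hetero**) are evidence of recombination
between minicircles — but only between circles that share a constant
region, which provides the homology. Distinguishing the two, and flagging
joins across incompatible constant groups as likely artifacts, is the
analytical core of the package.

## The synthetic-data generator

`build_species_model()` materializes a species: random constant-region
backbones at elevated GC, repeat units with per-circle unit-count ranges,
and random CDSs that are valid ORFs under genetic code 4 (ATG start,
terminal TAA, no internal TAA/TAG; TGA is tryptophan and is allowed as a
sense codon). The bundled default model is sized after the best-studied
species: 13 circles of roughly 2–4 kb, one gene each, in 3 constant groups
(one 11-circle group plus two singleton groups for *atp6* and LSU). CDS
lengths follow typical mitochondrial gene sizes; GC targets (0.48–0.53 for
cassettes, 0.60 for constant regions) encode the elevated GC these genomes
show. Realized GC concentrates on the target binomially, which the tests
check at 3 binomial standard deviations.

`simulate_reads()` draws, per read, a category from the mixture
(single / homo / hetero / background), a strand with probability 0.5
(double-stranded template), and injects errors with `mutate_sequence()`
(independent per-base substitutions and indels; qualities are a constant
Q20 placeholder because error lives in the sequence).

Design choices worth making explicit:

* **Single-read lengths** are truncated-normal, centred on the circle
  length with sd 10% of it, truncated below at 100 bp **and clamped above
  at the circle length**. The clamp is a physical statement: a once-nicked
  circle linearizes to at most its own length. Without it, draws above the
  circle length wrap the origin and contain more than one CDS copy — they
  *are* partial rolling-circle products, and labelling them "single" makes
  the truth table wrong, not the classifier.
* **Homo reads** are exactly `k` tandem copies (`k = 2 + Poisson(0.5)`),
  linearized at a uniform offset.
* **Hetero reads** follow the alternating
  cassette–constant–cassette–constant structure produced by recombination,
  joining two distinct genes from one constant group. Joins across groups
  require an explicit `allow_illegitimate` flag (default off), mirroring
  the observation that genes whose circles share no constant region are
  never found joined.
* **Concatemer rate**: the default mixture is 0.6% homo + 0.4% hetero.
  The study observed roughly 1% concatemers among collected reads but does
  not state a generative rate; 1% total is a modeling choice, not a
  measured parameter.
* **Background reads** are i.i.d. uniform-composition DNA: only the
  contrast with mitochondrial hits matters downstream.
* **Seeds**: one master seed; each operation derives a child stream by a
  fixed affine map, so modules are independently reproducible and identical
  (config, seed) pairs give byte-identical FASTQ output.

What a green test on this generator does *not* establish: real nanopore
error is not i.i.d. (homopolymer-biased indels), real libraries contain
ligation chimeras beyond the explicit concatemer model, quality strings
carry no information here, and repeat structure in real constant regions is
richer than the template model. Results on real data depend on filters the
generator cannot validate.

## Alignment and read collection

`align_reads()` is an affine-gap Smith–Waterman (match +2, mismatch −3,
gap open −5, gap extend −2; a length-L gap costs `5 + 2L`). Long
read/reference pairs are seeded with exact 13-mers; each seed cluster
window is solved by full dynamic programming, the optimal local alignment's
read interval is masked, and the flanks are re-searched, so one read can
yield several non-overlapping hits — the concatemer units. Identity is
matches / alignment columns with gaps counted as columns (the standard
BLAST-style reading). Minus-strand hits are reported in forward-read
coordinates.

Read-collection filters mirror the study's rules: `collect` keeps hits at
identity ≥ 0.80; `strict` additionally requires the hit to cover ≥ 80% of
the CDS at identity ≥ 0.90; `intron_rich` replaces coverage by a minimum
alignment length of 200 bp. Thresholds are applied per hit (the source is
silent on per-hit vs per-read aggregation). "Hit length" in the
intron-rich rule is alignment columns; CDS coverage in the strict rule is
measured on the reference interval.

A numerical caveat the tests encode: against a full Smith–Waterman oracle,
top-hit *scores* agree exactly on arbitrary pairs, but for unrelated random
sequences several co-optimal alignments of equal score can differ in
match/column composition, so *identity* is only compared on
high-similarity pairs where the optimum is essentially unique.

## Concatemer decomposition and classification

Hits are resolved greedily by score (≤ 20 bp read overlap tolerated for
end wobble) and walked in read order. The one subtle rule is copy
counting: a full-length read linearized *inside* the cassette shows the
same gene twice, separated by a constant stretch — but its two fragments
cover complementary parts of the CDS and sum to one copy. A same-gene hit
re-covering already-covered CDS positions (beyond max(20 bp, 10% of the
CDS)) is what opens a new unit. Copy number is total covered CDS bp / CDS
length, rounded; this cleanly separates wrapped single copies from tandem
duplications.

Categories: no gene unit → `non_mito`; one gene, one copy → `single`; one
gene, ≥ 2 copies, co-oriented → `homo` (inverted repeats are `ambiguous` —
rolling-circle products are tandem, never inverted); ≥ 2 distinct genes →
`hetero`, unless gene units overlap on the read (chimeric alignment →
`ambiguous`). "High confidence" is operationalized — the source gives the
phrase, not the rule — as: every gene unit covers ≥ 80% of its CDS *and*
every junction between gene units contains a constant unit covering ≥ 80%
of the constant region. Reproducing the study's exact high-confidence
count on real data is therefore not guaranteed.

## Annotation

* **Canonical rotation**: ORF-anchored by default (cassette first, matching
  how minicircle maps are drawn), lexicographic (Booth's algorithm) as the
  gene-free fallback. Both are idempotent and rotation-invariant.
* **ORF finding** runs six frames across the circular origin on the doubled
  string, under genetic code 4, requiring ATG (alternative starts are a
  flag; the source does not discuss start codons).
* **Segmentation**: a position of a circle is "constant" when local
  alignments (identity ≥ 0.90, ≥ 50 bp) to other circles cover it in a
  majority of its hit partners — never fewer than `min_share − 1 = 1`. The
  majority rule matters: with 10 partners, a single partner's chance
  local-alignment overhang would otherwise extend the union coverage ~30 bp
  into the cassette and smear the boundary. Gaps ≤ 30 bp are bridged
  (absorbing repeat unit-count differences), the longest circular run is
  the constant arc, and the complementary arc — which should contain the
  best ORF — is the cassette. Circles sharing nothing (singleton groups)
  are flagged low-confidence: their segmentation is undefined from sharing
  alone. Identical circles are flagged "whole circle constant" — no
  cassette is callable.
* **Grouping** is single-linkage on arc identity (total matched bp / longer
  arc length) at 0.80; cluster ids are the smallest member circle id, so
  the partition is input-order independent. Defaults (`min_share = 2`,
  `min_identity = 0.90`, `link_identity = 0.80`) are package choices — the
  source reports "high sequence similarity" with occasional SNPs but no
  thresholds.
* **Tandem repeats**: every maximal array with a primitive unit (period ≤
  40 bp) and ≥ 2 copies, fractional terminal copies included; floor the
  copy number when comparing against integer unit counts. Dispersed extra
  occurrences of a detected unit are reported with `tandem = FALSE`, since
  one repeat region in the motivating system is non-tandem. A unit that
  occurs only once in some circle is below the detector's definition of a
  repeat array there, so per-circle unit counts in the repeat catalogue
  are obtained by exact pattern matching of units detected anywhere in the
  set.

Repeat-region boundary conventions are original to this package; the
source does not describe how its repeat regions were delineated.

## Quantification statistics

Copy number from mass uses `x × N_A / (l × 660 × 10^9)` with the Avogadro
constant fixed at 6.02214076 × 10²³ and 660 g/mol/bp exactly as
conventionally printed. Standard curves are OLS of Cq on log10 copies;
efficiency is `10^(−1/k) − 1` (slope −3.32 ↔ 100%). Replicate Cq values
are averaged *before* interpolation, and the mito:nuclear summary is mean ±
sample (n−1) sd across mitochondrial genes; both orders of operation are
unstated in the source and fixed here as package policy. Cq values outside
the calibrated range are flagged as extrapolated rather than refused.

The rank-sum comparison is implemented internally: exact enumeration of
the permutation null of U (valid under ties) for `min(n) ≤ 8` and combined
`n ≤ 16`, else the normal approximation with tie and continuity
correction; two-sided p is `min(1, 2·min(P≤, P≥))`.

Contour conversions: microscopy calibration divides a measured contour
length by a known size in bp; fractional extension divides the resulting
nm/bp by the canonical 0.34 nm/bp B-DNA rise. The package returns raw
values; reporting at two decimals (0.24 nm/bp → 70.6%) is the caller's
convention, as in the worked example of `scripts/acceptance.R`.

## Degenerate inputs and tie-breaks

Empty gene lists, duplicate gene names, CDS lengths not divisible by 3,
rates outside [0, 0.3], mixtures summing over 1, unknown filter modes,
sub-3-point standard curves and zero-variance dilution series all raise
classed validation errors before compute. Ties in ORF anchoring resolve to
the smallest start (making rotation idempotent); ties in the length mode
resolve to the smallest length within the modal histogram bin; equal-score
alignment ties resolve by a fixed traceback preference (diagonal first).

## Known limitations

Concatemer breakpoints are not reconstructed at base resolution; there is
no spliced alignment, no SAM/BAM emission, no assembly, and no inference
of replication mode. Identity of the aligner's secondary hits depends on
the greedy masking order when hits overlap heavily. The acceptance-level
headline counts of the motivating study depend on deposited sequencing
data and unstated filter details, and are out of desk-scale reach by
design.
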