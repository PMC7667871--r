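---
title: "Methods: iCLIP analysis of an exoribonuclease and its planted-truth test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iCLIP analysis of an exoribonuclease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoclip)
```

## The problem

An exoribonuclease such as the archaeal exosome degrades RNA 3'→5' and, in
the reverse reaction, appends A-rich tails to RNA 3' ends. iCLIP
(individual-nucleotide resolution UV crosslinking and immunoprecipitation)
maps the protein's RNA contacts: reverse transcription usually truncates at
the crosslinked residue, so the crosslinked base is the nucleotide
immediately 5' of a cDNA read's start in transcript orientation. Three read
classes are informative and each needs its own treatment:

* **Linear reads** map end to end and yield crosslink sites and coverage.
* **Junction reads** cross the joint of a circular RNA, so their two
  fragments map in permuted genomic order and the read as a whole does not
  map.
* **Tail reads** carry a non-templated 3' suffix (the enzyme's A-rich
  tail) after a perfectly templated 5' anchor, and also fail to map.

`exoclip` implements the full chain — composite-barcode preprocessing,
unique-best mapping, junction and tail mining of the unmapped pool,
metagene crosslink profiling, and iCLIP/RNA-Seq enrichment — plus a
synthetic-data generator whose planted ground truth makes every stage
testable without any external download.

## Read preprocessing

Raw 75-nt reads carry a 9-nt composite 5' barcode: 3 random nt + a 4-nt
library (experimental) barcode + 2 random nt, followed by the cDNA insert
and, for short inserts, the 3' adapter `TGAGATCGGA`. The stage order is
fixed and deliberately mirrors the published FASTX-based chain:

1. remove the first base (poor sequencing quality);
2. quality filter: keep reads with ≥95% of bases ≥ Q5, then ≥90% ≥ Q20
   (boundaries inclusive on Phred+33 integers — the original tool's exact
   boundary semantics are ambiguous, so the inclusive rule is fixed here
   and tested);
3. collapse byte-identical reads (the random barcode is still attached, so
   it separates biological duplicates from PCR copies); collapsing before
   adapter clipping can in principle merge molecules whose only difference
   lay in clipped bases — the published order is reproduced rather than
   "fixed";
4. clip the adapter at its first full occurrence or at a 3'-terminal
   prefix of ≥5 nt (the published "manual trimming of remaining
   nucleotides" is under-specified; 5 nt is standard clipper behaviour and
   exposed as a knob);
5. demultiplex: drop 2 nt, match the next 4 nt exactly against the barcode
   table, drop 6 nt. Unmatched reads go to an `unassigned` bin.

Inserts shorter than 16 nt (the mapper's seed length) are discarded and
counted. Conservation (`input = survivors + removals` at every stage) is
asserted in the tests.

## Mapping

Desk-scale genomes do not need an FM-index aligner, and the acceptance
environment forbids external binaries, so `map_reads()` is an internal
ungapped end-to-end mapper: an exact-match fast path over a 16-mer hash
index (every exact full-length placement is found through the read's first
16-mer), with a mismatch-tolerant fallback (default ≤2 mismatches) for
reads with no exact placement. The published "MAPQ < 20 removed"
multimapper filter translates here to *unique best placement required*:
two or more placements tying at the best mismatch count make the read
`ambiguous`, and ambiguous reads are excluded from coverage and crosslink
analyses. Ties are never broken. The mapper is checked against a
brute-force Hamming scan over every offset and strand, including ambiguity
verdicts on a genome with a planted duplication.

## Circular RNA junctions

Unmapped reads are searched with a two-pass exact-fragment procedure that
renders the original two-pass blastn protocol deterministic:

1. **Primary fragment**: the longest exact genomic match of the read
   (both strands), minimum 20 nt; ties resolve to the plus strand, then
   the lowest genome coordinate. A read with no unaligned flank of at
   least the secondary seed length is dropped.
2. **Secondary fragment**: the longest exact match of the unaligned flank
   (3' flank first, then 5'), restricted to the primary's strand, minimum
   12 nt, within 4000 nt of the primary (measured between nearest fragment
   edges — the original protocol does not state which edges; this is a
   config knob), and at a *single* genomic location.
3. **Junction**: fragments must be permuted — on the plus strand the
   read-5' fragment lies genomically downstream of the read-3' fragment
   (mirrored on minus). `circ_start` is the genomic start of the read-3'
   fragment, `circ_end` the genomic end of the read-5' fragment.

When identical bases flank the joint, several (start, end) pairs describe
the same circle; calls are canonicalized by shifting the joint maximally
toward lower genome coordinates, so aggregation by coordinates is
well-defined. The generator plants circles at already-canonical
coordinates so recovery can be asserted exactly. Candidates require ≥10
supporting reads in ≥3 of the eligible (CoIP) libraries; control-library
counts are reported but never qualify a candidate.

Exactness (instead of blastn's near-exact word matching) is what makes a
clean independent oracle possible: the tests enumerate every (split
position, placement) explanation of a read by brute force and require
agreement.

## Non-templated 3' tails

After junction reads are excluded, a tail read is one whose 5' prefix
(anchor, 20 nt — aligned with the junction caller's primary minimum so the
two stages never claim one read with contradictory anchors) matches the
genome perfectly at exactly one location. The anchor is extended 3'-ward
while the read equals the template; the remaining suffix is the tail. The
maximal-extension rule means the reported tail is the *minimal*
non-templated suffix: when the genome itself continues in A's, reported
tails are systematically shortened. This bias is inherent to the
definition and documented rather than corrected. Reads containing N and
anchors with multiple locations are excluded (conventions fixed here).

Composition profiling counts bases per tail position (1..40) and overall;
by construction position-k counts are monotone non-increasing in k.

## Crosslink profiling

An HMM peak caller is replaced by deterministic truncation counting: a
plus-strand alignment starting at p yields a crosslink at p−1 (+); a
minus-strand alignment ending at e (half-open) yields e (−). This makes
every downstream profile exactly testable; it does not model
crosslinking noise, which is the main loss relative to a statistical
caller. Replicate libraries of the CoIP samples are merged by default.

* **Decile profiles**: each gene is split into 10 bins
  (`[floor((b-1)L/10), floor(bL/10))`, which exactly partitions any L);
  bins are ordered along the gene's 5'→3' direction. Crosslinks on the
  gene's strand are *sense*, opposite ones *antisense*, and antisense
  deciles are **not** flipped — they follow the host gene's orientation,
  so the 5' peak of an antisense RNA appears in the host's last decile.
* **Operon profiles**: member genes (same replicon and strand) are
  replaced by one artificial unit spanning min(start)..max(end).
* **Boundary profiles**: ±100 nt around gene starts/ends in transcript
  orientation, with no offset 0 (for the start anchor, −1 is the base
  immediately upstream; for the end anchor, −1 is the last gene base).
  Gene boundaries proxy UTR boundaries, defensible in an organism with
  largely leaderless mRNAs. Counts can be normalized to percent per
  window. Bin width 1 or any divisor of the window.
* **Motif windows**: ±10 nt genomic windows around selected crosslink
  sites, reverse-complemented for minus-strand sites, edge-truncated
  windows dropped — input for an external motif finder, which is out of
  scope.

## Enrichment and nucleotide content

Gene-level abundances use TPM: `TPM_i = (c_i/l_i) / Σ_j(c_j/l_j) × 1e6`,
conserving 1e6 by construction. Coverage-ratio summaries (iCLIP/RNA-Seq
per position, restricted to positions with RNA-Seq coverage, CDS and IGR
region classes) use type-7 (linear-interpolation) quantiles — the default
of the plotting environment the original figures came from — and report
zero-RNA-Seq positions separately. Enrichment at a locus uses the peak
(maximal per-base) coverage: rule A, iCLIP/RNA-Seq fold ≥2 in at least one
sample; rule B, an iCLIP peak (≥5 by default) where RNA-Seq is zero.
"Peak" is the simplest faithful reading of the published qualitative
language; a mean-based knob would be easy to add. Both tracks are scaled
to per-million by default for cross-assay comparability; the positional
CDS/IGR quartiles from the original study (median < 0.06, Q3 < 0.20/0.33)
are treated as qualitative context, not as numeric targets, because the
underlying normalization is not fully specified.

Per-CDS content statistics are the A fraction, A+G fraction and the
longest poly(A) run on the coding strand; IGR poly(A) discovery replaces a
blastn-with-(A)30 search by exact run-length scanning (for homopolymers
the run scan is strictly more sensitive and deterministic), reporting
plus-strand A-runs and T-runs (minus-strand poly(A)) truncated at IGR
edges, ranked by length.

## The synthetic world

The generator emulates exactly the features the pipeline exploits, with
defaults chosen once from the stated study conditions:

* six libraries with the published experimental barcodes
  (GGTT/TGGC/GGTC/CGGA/GGCA/CCGG), two of them controls;
* 75-nt reads, 9-nt composite barcode, adapter `TGAGATCGGA`, constant Q40
  qualities (quality realism is out of scope; a substitution-rate knob
  exists, default 0);
* truncation convention: insert starts one nt 3' of the crosslinked base
  in transcript orientation;
* linear insert lengths uniform 30–60 nt (the post-trim length
  distribution of the real libraries is unpublished; this range spans the
  20-nt primary and 12-nt secondary thresholds so the junction caller is
  genuinely exercised);
* tails: geometric lengths (mean 4, truncated at 40, matching the "very
  short" published tails and the 40-nt analysis cap) with per-position
  adenosine probability 0.73; the anchor position is rejection-sampled so
  the next templated base differs from the first tail base. This keeps
  planted tails non-extendable *without* altering the tail base law, so
  the detector recovers planted tails verbatim and composition recovery
  can be tested at the planted probabilities;
* junction reads split ≥25+≥25 nt across planted, canonical circles;
* PCR duplication: copies = 1 + Poisson(max(0, rate − 1)), so rate 0
  yields exactly one read per molecule and every molecule survives
  (conservation); the expected copy number equals the rate for rates ≥ 1.
  Default rate 2;
* a designed convergent gene pair with 30-nt overlapping 3' ends and
  tRNA/rRNA biotypes, so antisense and biotype analyses have substrate;
  gene lengths are multiples of 10, which makes decile bins exactly equal
  and the uniformity null exact;
* RNA-Seq reads uniform within genes, proportional to per-gene abundance.

What a green test establishes — and what it does not: the synthetic world
has no sequencing errors by default, no crosslinking bias, no structure-
or expression-dependent coverage, and genomes are i.i.d. random (real
genomes have repeats far beyond the one planted duplication used to test
ambiguity). Green tests certify the *computational* contracts: exact
recovery of planted signal, correct conventions, conservation laws, and
statistical calibration under the stated noise model.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere, stated so quartile outputs are
  reproducible.
* Chi-square uniformity on deciles uses expected counts proportional to
  bin widths (equal here by construction), α = 0.01, and ≥95/100 seeds.
* Empty inputs return typed empty results (empty read tables, zero
  tracks, empty profiles with n = 0) rather than errors; all-zero count
  vectors are an error in TPM (no normalizer exists).
* Genes shorter than 10 nt are excluded from decile profiles (cannot
  happen with the generator, which enforces length ≥ 100).
* Ties in the mapper are never broken (ambiguous); ties in fragment
  search break deterministically (+ strand, lowest coordinate).

## Known limitations

* The crosslink caller is deterministic counting, not a statistical peak
  model; replicate-aware peak calling is out of scope.
* The mapper is ungapped; indel-containing reads are unmapped (at desk
  scale with error rate 0 this loses nothing, on real data it would).
* Junction and tail detection are exact-match based; highly mutated reads
  fall out of both and remain in the residual unmapped pool.
* The acceptance criterion that reproduces published CDS-content numbers
  for the pinned RefSeq genome needs that ~3 MB download; in offline runs
  it stays red with an explanatory message. The computation itself
  (`cds_content()` and the `content` CLI) is implemented and tested on
  synthetic sequence sets against an independent run-scan oracle.
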