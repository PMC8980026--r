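---
title: "Methods: comparative mitogenomics with mitocomp"
author: "mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

`mitocomp` implements the statistics a comparative mitogenomics study of
teleost fish runs over annotated mitochondrial genomes, with the Indian
scad *Decapterus russelli* (16,542 bp; 13 protein-coding genes, 22
tRNAs, 2 rRNAs, one control region) as the shipped worked example. This
vignette explains the models and conventions behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the package's known limitations.

## The genome model

A `mitogenome_record` holds a genome length, an optional H-strand
sequence, and an ordered feature table in 1-based inclusive coordinates,
the convention of GenBank flat files and of published annotation tables.
Light-strand (L) features are stored in H-strand coordinates; their
coding-strand sequence is the reverse complement of the H-strand slice,
taken at extraction time. This is what makes the ND6 row of a
per-region composition table T/G-rich while its H-strand slice is
A/C-rich: the statistics are computed on the strand the gene is actually
read from.

Origin-spanning features are not modelled (none occur in the worked
example); the `circular` flag is carried for completeness and the
junction walk can optionally close the circle. Feature adjacency uses
genome order regardless of strand, because annotation tables publish a
single intergenic column: the junction between consecutive features is a
*spacer* (gap > 0), an *overlap* (shared bases, e.g. the 7 bp shared by
ATP8 and ATP6), or *adjacent* (distance exactly 0). A junction can never
be both a spacer and an overlap, and recomputing every feature size from
its coordinates must reproduce the printed size column — the package's
first validation on any imported table.

## Composition, skews, codons

Base composition is reported as percentages of the unambiguous (non-N)
length; N above 10% of a region triggers a warning. AT skew
$(A-T)/(A+T)$ and GC skew $(G-C)/(G+C)$ are computed from full-precision
counts; rounding is display-only. The `"paper"` rounding profile (the
default in report tables) rounds percentages to 1 decimal and skews to
3 decimals, half away from zero — this is the convention that turns the
control region's $(33.0-30.6)/63.6 = 0.03774$ into the published 0.038.
A skew whose denominator is zero is reported as missing, never as 0.

Stop codons are classified from gene length modulo 3: a remainder of 1
is a `T--` incomplete stop, 2 is `TA-`, and 0 a complete stop checked
against the vertebrate mitochondrial stop set (TAA/TAG/AGA/AGG).
Incomplete stops are completed to TAA by polyadenylation of the mRNA;
six genes of the worked example end this way.

## Codon usage and RSCU

Codons are read in frame from position 1 of each annotated gene (no
frame search), the trailing partial codon of an incomplete stop is
dropped, and codons containing N are skipped and tallied. The genetic
code is the vertebrate mitochondrial table (ATA = Met, TGA = Trp,
AGA/AGG = stop), making Leu the one six-codon family. Amino-acid
frequencies are percentages of *all* in-frame codons, stop codons
included under `*` — whether the published residue frequencies include
stops in the denominator is not stated, so the package includes them and
says so here; at ~3,800 codons the difference is under 0.1 percentage
point.

RSCU for codon $j$ in a family of size $n$ is
$X_j \, n / \sum_k X_k$: 1 means unbiased use, 0 an unused codon of an
observed family; a family with zero observations has RSCU missing, not
zero. Stops are excluded from RSCU by default. Two identities are
enforced by tests: every observed family's RSCU sums to the family size,
and RSCU is invariant under scaling all counts.

## p-distances and Ka/Ks

`p_distance` is the proportion of differing sites with *pairwise*
deletion: columns with a gap or N in either member of a pair are dropped
for that pair only. The partition (`all`, `pos12`, `pos3`) selects codon
positions before comparison; the mean is over unordered pairs, and the
package labels it as such (whether the published "overall" distance is a
pairwise mean or a pooled statistic is not stated).

Ka/Ks uses classic Nei–Gojobori (1986) counting — the published analysis
names only the software it used, so the package implements and documents
the reference algorithm rather than guessing a variant, and exposes the
uncorrected `pN`/`pS` alongside. Per codon, each position contributes
the fraction of its three possible changes that are synonymous;
differences at multi-hit codons are averaged over all minimal pathways
with equal weights; changes to (and pathway steps through) stop codons
count as nonsynonymous. $p_S = S_d/S$ and $p_N = N_d/N$ are corrected
with Jukes–Cantor, $d = -\tfrac34 \ln(1 - \tfrac43 p)$, undefined at
$p \ge 3/4$ and reported missing with a reason. Gap/N codons are removed
pairwise before counting; a shared trailing stop is trimmed; an internal
stop is a hard error, because it means the alignment is out of frame.
The test suite checks the implementation against an independently coded
brute-force pathway-enumeration oracle on short pairs, and against exact
limits (simulated pure synonymous drift gives $K_a = 0$ exactly).

## tRNA cloverleaves and wobble pairs

Structures are *consumed* as dot-bracket strings, never predicted. The
parser requires 3 or 4 strictly stacked helices: the outermost is the
acceptor (AA) stem; internal helices in 5'→3' order are DHU, anticodon
(AC) and TΨU; a 3-helix structure is the tRNA-Ser(GCT) case, with the
first internal helix taken as AC. Bulged stems would split into extra
helices and are rejected — a deliberate strictness, since the shipped
generator and typical tRNA annotations produce clean stems.

Base pairs are Watson–Crick ({A,T/U}, {G,C}), G–U wobble, or a named
mismatch (alphabetically ordered, e.g. `A-C`). Per-site tallies use a
canonical 25-site map in a fixed 1–88 numbering: 8 AA sites
(`1-87` … `8-80`), 5 DHU (`11-33` … `15-29`), 6 AC (`35-53` … `40-48`),
6 TΨU (`60-78` … `65-73`). The two published DHU anchor labels (12–32
and 15–30) are mutually inconsistent with nested pairing, so the map
interpolates with a constant offset from 11+33; site `15-30` is `15-29`
here. Anchoring is outermost-first for the AA stem and innermost-first
for the three arms, so a 4-bp DHU stem occupies `12-32` … `15-29` and
the loop-closing pair keeps its label as stems shorten. Wobble
percentages use as denominator the pairs actually present, so short
stems contribute fewer pairs, matching per-tRNA "total base pairs"
bookkeeping.

The H- versus L-strand comparison is a two-sided Mann–Whitney U test on
per-tRNA wobble percentages via `stats::wilcox.test` (exact for small
untied samples, normal approximation with tie correction otherwise).

## Control-region annotation

Motif scanning minimizes unit-cost edit distance of the reference motif
against the region (`Biostrings::pairwiseAlignment`, match 0, mismatch
−1, gap −1, pattern-global/subject-local), with an exact-substring fast
path that guarantees the leftmost verbatim occurrence; with zero budgets
the scan *is* exact substring search, a property the tests verify
against a naive oracle. A hit must respect both the substitution and the
indel budget; defaults are 9 substitutions (the maximum divergence
observed across the published species panel) and 2 indels, per-motif in
the shipped library. Divergence masks serialize a global alignment to
plain text — `*` identity, uppercase base = substituted query base,
lowercase = insertion, `-` = deletion — replacing the published
bold/underline typography with a bit-exact convention; applying a mask
to its reference reconstructs the query exactly.

The shipped library splits the published concatenated central-block
reference into CSB-F (20 nt), CSB-E (18 nt, containing the GTGGG box)
and CSB-D (24 nt), and the conserved-block reference into CSB-1 (24),
CSB-2 (20) and CSB-3 (23); the split is a recorded convention of this
library, editable in `inst/extdata/csb_motif_library.tsv`. The annotator
checks the canonical order CSB-F < E < D < 1 < 2 < 3 (violations warn
but hits are still reported), finds the GTGGG box as a sub-motif of the
CSB-E hit, exact TACAT/ATGTA palindromes (reverse complements of each
other), maximal T-runs of ≥ 5 nt flagging the one between CSB-D and
CSB-1, and tandem repeats. The repeat scan is exhaustive and exact (unit
2–20 bp, ≥ 3 copies) with two guards: the unit must be its own minimal
period (a T homopolymer is not a TT-repeat), and a run must span ≥ 12 bp
— without the span threshold any random AT-rich 840-mer contains several
chance 3-copy dinucleotide runs, which no practitioner would call
repeats; standard repeat finders impose an equivalent minimum score.
Extended termination-associated sequences (ETAS) are not modelled: they
could not be aligned across the study species.

## The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. Its defaults are the study conditions: the 38-feature layout at
the printed coordinates; H-strand base probabilities A 0.275, C 0.302,
T 0.254, G 0.169; an AT-rich control region (A 0.330, T 0.306, G 0.163,
C 0.201); tRNA groups of 14 H- and 8 L-strand genes with per-pair wobble
probabilities 0.03 and 0.13. One seed determines all output.

Protein-coding genes are written in frame with the layout's start codon
and complete/incomplete stop; L-strand genes are written as reverse
complements; the mTERF tridecamer `TGGCAGAGCCCGG` is planted inside
tRNA-Leu(TAA); the control-region span is generated with motifs planted
in canonical order, each mutated by exactly the requested substitutions
and indels at recorded interior positions. The control-region builder
*verifies its own ground truth*: the background is resampled
(deterministically under the seed) until every planted motif is the
scan's best hit at its recorded position and counts, so downstream
recovery tests are exact rather than probabilistic. This guarantee has
an information-theoretic limit: a motif mutated at half its positions
(e.g. 9 substitutions on an 18–24-mer) is no longer uniquely locatable
in 840 bp of background — random windows reach the same edit distance —
so the builder rejects such requests with an explicit error rather than
record a ground truth it cannot honour. Recovery tests therefore plant
up to 5 substitutions; scanning budgets up to 9 remain supported.

What the generator does *not* emulate: phylogenetic correlation between
species (taxa are independent draws, not a tree), codon usage bias
beyond base composition, mismatch pairs in tRNA stems (probability 0 by
default), transcription-strand asymmetries within genes, and
heteroplasmy. Passing tests on generator data therefore demonstrate
bookkeeping correctness and statistical calibration, not biological
realism of any particular inference on real genomes.

Where the layout makes genes overlap (ATP8/ATP6, ATP6/COIII, ND4L/ND4,
ND5/ND6), the later feature's bases win — as they must on a single
molecule — so the earlier gene's planted tail is overwritten; ground
truth records the pre-overwrite coding sequences, and tests on planted
codons use unclipped genes.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
oracle cross-checks use ≤ 10-codon pairs (pathway enumeration is
factorial in the differences per codon, which is at most 3! = 6);
RSCU checks use 200-codon draws; tRNA tallies use 2–5 replicate species
sets (≈ 40–100 pairs per tRNA, comfortably over the ~500 pairs per
strand group needed for the 3% vs 13% contrast); the power simulation
runs 200 replicates of the 14-vs-8 Mann–Whitney comparison. Rounding is
half away from zero everywhere a display value is produced; ties in
motif scanning are broken toward exact matches and otherwise resolved by
the aligner; all randomness flows from a single integer seed per
generator call.

## Known limitations

* Annotation is consumed, never inferred: no gene finding, no tRNA
  prediction, no origin-of-replication modelling.
* Tree inference, divergence dating and secondary-structure folding of
  CSB motifs are out of scope; the annotator exposes motif sequences so
  an external folder can be applied.
* The Ka/Ks estimator is the counting method with Jukes–Cantor
  correction; maximum-likelihood dN/dS and site-specific selection tests
  are not provided.
* The GenBank reader handles single-interval (optionally complemented)
  gene/tRNA/rRNA/D-loop features — sufficient for mitogenome records,
  not a general flat-file parser.
* The published per-region table contains a handful of internally
  inconsistent cells (a tRNA skew outside [−1, 1], duplicated ATP8/ATP6
  compositions, a whole-genome GC skew inconsistent with its own
  composition); the shipped fixture carries the printed values, and the
  package's validation warns rather than silently correcting.
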