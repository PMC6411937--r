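---
title: "Digestion diagnostics for ribosome profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digestion diagnostics for ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboqc)
```

## Scope and assumptions

`riboqc` diagnoses the completeness of RNase digestion in ribosome
profiling libraries from sequence-level properties of the footprints
themselves, and provides a simulator whose single controlling parameter —
digestion completeness — reproduces the observable syndrome of
under-digestion. Everything operates in transcript space: footprints are
intervals on annotated transcripts (0-based, half-open coordinates), each
transcript a `[5'UTR)[CDS)[3'UTR)` partition with a CDS that starts at
`AUG`, ends at a stop codon and has length divisible by 3. Genome-space
concerns (introns, junction reads, multimapping resolution, rRNA
alignment) are upstream of this package: alignments arrive already
categorised, and the contaminant categories are passed through, not
recomputed.

## The diagnostic metrics

**Windowed GC.** Composition is computed per 5'-anchored position: the
fraction of reads of length at least `p` carrying each base at `p`. Reads
shorter than `p` leave the denominator rather than being padded — with
mixed 26–34 nt footprints any fixed denominator would distort the tail
positions. The GC diagnostic averages the per-position G+C fraction over a
1-based inclusive window, by default positions 10–20 (11 positions) for
footprints and 10–65 for mRNA-seq reads. Averaging per-position fractions
(rather than per-read GC) matches how the window is read off a composition
plot; for reads of a common length spanning the window the two definitions
coincide, which is asserted in the tests. The window convention itself is a
choice — "positions 10–20" does not say whether ends are inclusive — and is
documented rather than configurable-by-accident.

**Length peak.** The mode of the length histogram represents the sample;
ties break toward the smallest length, so a flat-topped histogram reports
the most-digested plausible value. Complete digestion puts the mode at
28 nt, the canonical 80S footprint.

**Region assignment.** Each footprint is assigned to the region containing
its P-site, not to every region it overlaps; a 28 nt read straddling the
start codon is one ribosome, not one 5'UTR read plus one CDS read. An
`"overlap"` mode (count a read toward every region it touches, as a
bedtools-style intersection would) is available for comparability, with
fractions then defined over assignments.

**P-site offsets.** For each read length `L` the offset is the argmax over
`o ∈ [L/4, L/2]` of the aggregated 5'-end density at `CDS_start − o` — the
start-codon metagene method. The search interval excludes degenerate maxima
near the read ends. A peak-to-mean density ratio below 2 flags the estimate
low-confidence; lengths with fewer than 200 reads inherit the read-weighted
modal offset of the estimated lengths. This estimator *requires* an
initiation peak in the data: with perfectly uniform ribosome positions the
start-codon density is periodic in 3 and the argmax is a coin flip between
offsets 12 and 9 (for `L = 28`). Real libraries always carry an initiation
peak; the simulator therefore includes one (below).

**Frame preference.** The P-site frame is `(P-site − CDS_start) mod 3` for
CDS-mapped reads, tabulated per length; the reported "best" frame
resolution is the maximum frame-0 fraction across lengths with at least 100
CDS reads (ties toward the shorter length), mirroring how a single number
summarises periodicity across a length distribution.

**Metagene profiles.** Per-nucleotide P-site counts along one transcript,
normalised either to library size (counts per million mapped reads) or to
the mean CDS density of that transcript, averaged across replicate samples,
then smoothed with a centred moving average. A nominal window of 30 nt is
widened to 31 to stay centred; windows truncate at the transcript ends so
that uniform coverage is a fixed point of the smoother and total signal is
conserved up to edge truncation.

## The simulator's digestion model

`digestion_params()` exposes the model; `completeness` (`c ∈ (0, 1]`) is
the scientific quantity, everything else a bias strength:

| parameter | default | meaning |
|---|---|---|
| `length_peak_complete` | 28 nt | modal footprint at complete digestion |
| `length_shift_max` | 5 nt | modal shift at `c → 0`; mode is `28 + round(5(1−c))` |
| `gc_bias_strength` (β) | 12 | GC acceptance tilt `exp(β(1−c)(GC−0.5))` |
| `frame_fidelity_complete` / `_floor` | 0.9 / 0.4 | P-site in-frame probability `floor + (0.9−floor)·c` |
| `utr_contamination_max` | 0.3 | UTR read fraction `0.3(1−c)` |
| `end_bias` | A-rich 5', no-A 3' | RNase A+T1 cut chemistry |
| `pcr_dup_rate` | 0.1 | geometric PCR duplication |
| `init_peak_weight` | 5 | start-codon P-site enrichment |

Design notes, in the order the choices were actually contentious:

* **Length family.** Only the mode (28 nt) and the gel size-selection
  window (26–34 nt) are physically anchored; the family connecting them is
  free. A discretised binomial over `mode − 4 .. mode + 6`, truncated to
  the gel window, is unimodal, mildly right-skewed and two lines of code;
  nothing downstream depends on more than the mode and a few nt of spread.
* **GC bias as acceptance tilt.** Under-digestion enriches GC-rich
  footprints; the mechanism is not modelled, only the effect. An
  exponential tilt on candidate fragments is the maximum-entropy way to
  shift a mean without further commitments. β = 12 makes the fully
  incomplete limit raise windowed GC by roughly
  `β · Var(GC) ≈ 12 · 0.0083 ≈ 0.08`, i.e. ~8 GC points — the scale that
  separates badly affected from clean libraries.
* **Region quotas before acceptance.** The UTR contamination fraction is a
  model *contract* (`0.3(1−c)`), but a naive implementation breaks it: the
  GC tilt would preferentially reject AT-rich UTR fragments and more than
  halve the realised contamination. The sampler therefore fixes
  multinomial region quotas first and applies the GC/end-bias acceptance
  within each region.
* **P-site geometry.** In-frame reads of length 28 carry their P-site
  12 nt from the 5' end (the common convention); extra length from
  under-digestion is modelled as 5'-side extension, so the truth offset is
  `12 + (L − 28)`. Out-of-frame reads shift the P-site ±1 nt.
* **Initiation peak.** `init_peak_weight` gives the start codon a 5-fold
  P-site weight over other codons. It is not part of the digestion
  syndrome; it exists because the offset estimator (and real data) needs
  the landmark. Setting it to 1 removes it.
* **End biases.** RNase A cuts after pyrimidines and T1 after G, so
  fragments essentially never end in A (3' weight 0.05) and observed 5'
  ends are A-enriched (weight 2.5). The 5'-A enrichment is an observed
  regularity whose mechanism is unclear; it is a free weight, not derived.
* **Random streams.** UMI assignment and PCR duplication run on RNG
  streams derived separately from the sample seed, so changing
  `pcr_dup_rate` leaves the fragments untouched. Fragment generation
  (transcript, length, position, frame, acceptance) shares one stream:
  rejection sampling couples those draws, and pretending otherwise would
  promise an isolation the sampler cannot keep.
* **Duplication.** Each unique fragment gets `1 + Geom(1 − r)` copies, so
  the expected duplicate fraction of the emitted reads is exactly `r` — a
  closed form the tests exploit.
* **Qualities.** Constant Q37; the package models digestion, not the
  sequencer.

### Why the complete-digestion footprint pool sits at ~50% GC

Mammalian CDS averages ~60% GC, and the transcriptome generator's default
CDS target is 0.60. Yet cleanly digested libraries consistently show ~50%
GC footprints — the footprints that survive complete digestion are not an
unbiased sample of CDS, plausibly the most RNase-resistant subset. The
simulator does not model that mechanism (its GC tilt vanishes at `c = 1`,
where footprints faithfully sample their source). Where the package's own
validation needs the *absolute* complete-digestion signature (~50% GC,
28 nt), it therefore simulates from a footprint-pool transcriptome at CDS
GC 0.50, representing the digestion-resistant pool directly; the
*correlational* diagnostics are invariant to this choice. This is the one
place where the simulator's defaults distinguish "the mRNA in the lysate"
(GC 0.60) from "the pool complete digestion samples" (GC 0.50).

## Read preparation

The default read layout is `[5 nt barcode][8 nt UMI][insert][3' adapter]`,
expressed as a config object rather than hard-coded, since layouts vary by
protocol. Demultiplexing requires the whitelist to have pairwise Hamming
distance greater than `2 · max_mismatch` (default mismatch budget 1) and
errors otherwise — silent ambiguous assignment is worse than a loud
configuration error. Adapter trimming is 3'-anchored prefix matching
without indels: every start position where an adapter prefix of at least 5
nt can run to the read end is scored as matches minus mismatches, subject
to a 10% mismatch rate cap; among equal scores the earliest start wins,
trimming more rather than less (conservative against adapter
read-through). Indel-aware alignment is out of scope; at these overlap
lengths indels are rare and the cost asymmetry (losing 1–2 insert bases vs
leaving adapter in) favours simplicity. The accounting invariant
`assigned + unassigned + dropped = input` is checked in tests.

## Deduplication

The duplicate key is `(reference, start, strand, length, UMI)`: footprints
differing at either end are different molecules even under an identical
UMI. Keying on UMI alone would merge distinct fragments whenever a UMI
recurs by chance (a certainty at realistic depths with 8 nt UMIs); the
coordinate-inclusive key is the conservative reading. UMI matching is
exact; sequencing-error-tolerant (directional-cluster) merging is a known
refinement deliberately left out, since the simulator emits error-free
UMIs and the conclusions the package tests do not turn on it. The first
read encountered in each class is retained, so the retained key multiset is
order-invariant even though the representative is not.

## Titration analysis

Step `k` of a titration uses `base · fold^(k−1)` of each enzyme (defaults:
4.8 ng RNase A and 0.6 U RNase T1 per µg RNA, 5-fold, 5 steps, 2 µg RNA in
0.3 ml, 25 °C, 30 min). The correlation axis is `log_fold` of relative
concentration — i.e. simply `k − 1` — so that "log5 scale" is exact for the
default series. GC/length qualification tolerances for the recommendation
(±2 GC points, modal length within `[target, target + 1]` nt) are artifact
decisions; the underlying targets (~50% GC, 28–29 nt) come from the
complete-digestion signature. Monosome disassembly cannot be inferred from
sequence data — it is a sucrose-gradient judgement — so it enters as an
operator-supplied flag per step, and the recommender never selects a
disassembled step: if nothing qualifies it falls back to the highest
intact step with a warning, preferring over-digestion to under-digestion.

## Expression QC

Counting uses P-sites within the CDS trimmed by 30 nt at each end,
avoiding the initiation and termination peaks; genes with mean count below
5 across samples are filtered. The log transform is median-of-ratios size
factors followed by `log2(x/sf + 1)` — a deliberate, documented stand-in
for the regularised log: absolute values differ, but the correlation and
PCA structure that QC consumes is preserved, and the size factors
themselves are cross-checked against an independent estimator in the
tests. PCA takes the 1000 most variable genes (or all, if fewer), centred
but not scaled — scaling to unit variance would let near-constant genes
inject noise. The hypergeometric overlap test requires an explicit
universe: the correct universe (all expressed genes after filtering vs all
annotated genes) is a scientific choice with order-of-magnitude impact on
the p-value, so the package refuses to guess. The average silhouette width
(plain Euclidean form) on PC1 quantifies which design factor dominates;
it is implemented directly as a ~20-line utility.

## Numerical and degenerate-input behaviour

Zero-variance metrics across titration steps yield `NA` correlations with
a warning rather than `NaN`; hypergeometric tails are computed in log
space; constant expression matrices flag the PCA as degenerate; empty
FASTQ files round-trip; a window exceeding the profiled read length is an
error, not a silent `NA`. Ties are broken deterministically everywhere
(smallest length, earliest adapter start, lowest offset) so repeated runs
agree exactly, and the simulator is byte-deterministic given its seed.

## Problem sizes and what the tests do and do not show

The validation suite simulates 150–200 transcripts and 1,000–20,000 reads
per sample (20,000 per titration step; eight samples of 15,000 for the
factorial batch/genotype designs) — sizes at which every stochastic check
has comfortable margin while the full suite runs in about two minutes. The
simulator emulates the digestion-completeness syndrome, not sequencing:
there are no base-call errors, no indels, no rRNA/tRNA reads beyond
pass-through labels, no genome-space alignment ambiguity, and transcript
abundances are log-normal with independent genes. Passing tests therefore
demonstrate that the *metrics recover the model that generated the data*,
and that this model reproduces the qualitative phenomenology of real
digestion series; they do not certify behaviour on artefacts the simulator
does not contain.
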