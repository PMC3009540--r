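---
title: "Discovering anchored protein sorting motifs from impure sequence sets"
author: "AnchorMotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering anchored protein sorting motifs from impure sequence sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AnchorMotif)
```

## The problem

Protein sorting signals — the "postal codes" that route a newly synthesized
protein to its compartment — are short sub-sequences, usually within the
terminal 200 residues. A recurring architecture is an *anchored* motif: a
2–5 residue, nearly invariant core (the twin-arginine RR of Tat-pathway
signal peptides, the NPxY of LDL-receptor cytoplasmic tails) surrounded by a
flanking region that is conserved only in its physicochemical character
(hydrophobicity, charge), not at the residue level. Alignment-based motif
finders handle the anchor but miss the weak flanks; this package formulates
discovery as a *classification* problem instead: a motif model is good
exactly insofar as it separates sequences sorted to a location from
background sequences.

A second, practical obstacle is that positive sets are rarely pure. Several
transport pathways target any one compartment, so a set of "proteins sorted
to L" typically contains many sequences that carry no instance of the motif
being sought. The package therefore includes an iterative
false-positive-removal procedure that discards positive sequences unlikely
to carry a true instance before the motif is finalized.

## The model and the pipeline

**Window classifier.** The core statistical object is a two-class naive
Bayes model over fixed-width residue windows (width $W$, default 10). For
class $c$ and window column $j$, residues follow an independent categorical
distribution estimated with Laplace smoothing
$\hat p_{c,j}(i) = (n_{c,j}(i) + \alpha)/(N_{c,j} + 20\alpha)$, with
$\alpha = 1$ by default — with a 20-letter alphabet and a few hundred
windows, unsmoothed columns would yield zero likelihoods. All products are
accumulated in log space (no underflow for any realistic $W$). An `X`
(any ambiguity code) is excluded from training counts and contributes a flat
$1/20$ likelihood to both classes at scoring time, so it is informationless.

**Pipeline.** `discoverMotifs()` runs:

1. *Preprocessing* — terminal segments (first/last $K = 200$ residues) are
   extracted; optionally, redundancy is removed by greedy longest-first
   clustering at 80% identity (`reduceRedundancy()`), because near-duplicate
   training sequences bias the classifier and inflate cross-validation.
   Identity is computed from a global alignment (match 1, mismatch 0, linear
   gap −1) as identical positions over alignment columns including gaps.
2. *Frequent anchors* — every instantiation of the gapped template
   `<residues>{n} <gap>{min,max} <residues>{m}` is counted in the positive
   segments (`enumerateAnchors()`). Patterns are ranked by the number of
   distinct supporting sequences (a sorting signal occurs once or twice per
   protein, so per-sequence support resists repeat-rich outliers), ties
   broken lexicographically. Anchors below 30% support are skipped by
   default: downstream purification tolerates substantial impurity, but not
   that much.
3. *False-positive removal* (optional, `purifyPositives()`), below.
4. *Boundary determination* (`determineBoundaries()`) — a width-$W$ window
   slides outward from the anchor; at every offset a window model is trained
   and scored by stratified 5-fold cross-validation; extension in a
   direction ends at the first offset whose min(precision, recall) falls
   below 0.5 (chance level).
5. *Motif score* (`motifRegionScore()`) — the boundary-delimited instances
   are cross-validated against equal-width background windows;
   min(precision, recall) is reported, which cannot be gamed by class
   imbalance.

**Background windows.** Wherever background windows are needed, a negative
sequence that itself contains the anchor contributes its anchor-aligned
window (sliding with the same offset as the positives); only anchor-free
negatives contribute randomly placed windows. This anchor-matching is
essential: the anchor residues are present at fixed columns of *every*
positive window, so against purely random background windows a classifier
would separate the classes almost perfectly from the anchor alone, and the
score would measure anchor frequency rather than flank conservation.

**Occurrence seating.** A sequence often contains several anchor
occurrences (an implanted or true motif plus coincidental matches). Each
round, a seat-window model is trained from the current seating and every
sequence's occurrence is re-chosen as the one with the highest seat-window
posterior (leftmost initialisation, ties to the leftmost). Without this
small EM-like refinement, a fifth or more of genuinely motif-bearing
sequences would sit on a coincidental upstream anchor and be scored — and
in removal mode, discarded — as false positives.

## False-positive removal

For each anchor, the procedure iterates:

1. seat a window at each positive's chosen anchor occurrence; background
   windows come from the negative set as described above;
2. train the window model at the current offset;
3. score every positive's window (posterior of the motif class);
4. advance the window one residue at a time — leftward, then rightward from
   the seat — retraining at every offset, until each sequence has had
   `consecutiveLow` (default 3) successive scores below `scoreThreshold`
   (default 0.85), or its segment edge intervenes;
5. average, per sequence, the scores accumulated *before* its terminating
   run of consecutive lows (both directions pooled; a sequence whose scan
   begins inside such a run is averaged over the run itself) and remove
   sequences with mean below the threshold;
6. repeat on the reduced set until no removal occurs or `maxIterations`
   (default 10) is reached.

The pre-run averaging in step 5 matters. A true-motif sequence scores high
across the motif and then — like every sequence — drops to chance once the
window leaves it; averaging over *all* visited offsets would therefore drag
every sequence below any useful threshold. Averaging the scores a sequence
produced before its own terminating low-run measures how long and how
strongly its neighbourhood stayed motif-like, which is the quantity that
separates carriers from non-carriers. Scoring is deliberately in-sample
(the model is trained on the very windows it scores), as befits a data
*cleaning* step; all reported motif quality, by contrast, is
cross-validated.

## Boundary placement

The sliding-window scan is a biased boundary estimator: with $W = 10$ a
window can keep min(precision, recall) above chance while only one or two
conserved columns still overlap it, so the outermost passing window's outer
edge overshoots the true boundary by almost a full window. The boundary is
therefore placed at the *center* of the outermost passing window
(`centerCorrection`, default $\lfloor W/2\rfloor + 1$). On 20-residue
implanted motifs this yields detected lengths of about 26–28 residues —
an over-extension of 3–4 residues per side, the behaviour expected of
sliding-window boundary detection at this window width. Setting
`centerCorrection = 0` reports the raw outer edge.

## Motif summaries

`informationContent()` measures conservation in bits,
$\mathrm{IC} = \sum_{j=1}^{L}\left(\log_2 20 + \sum_i p_j(i)\log_2 p_j(i)\right)$,
with observed frequencies, no pseudocount, $0\log 0 = 0$, and `X` excluded
from a column's counts; a fully conserved column contributes
$\log_2 20 \approx 4.32$ bits. `buildPWM()` returns column frequencies and
a consensus in the field's conventional rendering: the modal residue where
its frequency reaches 0.5, otherwise `x` (so NP.Y-like instance sets print
as `NPxY`). PWMs can be exported in MEME minimal format
(`writeMemeMotif()`) for logo tools; no graphics are produced in-core.

## The synthetic benchmark

`runBenchmark()` reproduces a controlled implanted-motif design:

* background — i.i.d. sequences over the average Swiss-Prot amino-acid
  composition (shipped as a plain-text fixture), 219 positive and 220
  negative sequences of length 200 by default;
* implant — a 20-residue motif, anchor `AA`, flanks drawn i.i.d. from a
  restricted alphabet (hydrophobic {V,I,L,M,F,W,C}, optionally plus charged
  {K,R,D,E}, or the full alphabet for an anchor-only control) with
  frequencies equal to the background composition renormalized to that
  alphabet, overwritten at a uniformly random start within the first 100
  residues (substitution keeps lengths and coordinates stable);
* purity — a `trueRatio` of the positive set receives the implant; ground
  truth (who, where) is returned for recovery statistics;
* replication — dataset seeds derive only from the global seed, flank
  class, true ratio and replicate index, so removal/no-removal contrasts
  run on identical data. Three replicates per condition keep a full sweep
  in the tens of seconds; ten replicates mirror a full protocol.

What the generator deliberately does *not* emulate: real proteins are not
i.i.d. — they carry repeats (poly-A runs inflate coincidental `AA`
anchors), domain-scale composition heterogeneity (hydrophobic stretches
that mimic a hydrophobic-flank motif), and phylogenetic redundancy. Passing
benchmarks here therefore demonstrate correctness of the machinery and the
qualitative behaviour of purification, not performance on curated
Swiss-Prot sets; on real data the no-removal baseline tends to degrade
*faster* with impurity than on i.i.d. backgrounds, where weak uniform noise
is the hardest case for the contrast. Real FASTA inputs are supported
directly through `readFastaDataset()`/`discoverMotifs()` and the
command-line script in `inst/scripts/`.

## Numerical and design choices

* Coordinates are 1-based closed intervals, the Biostrings convention.
* Stratified CV folds come from a single seeded shuffle; precision/recall
  are pooled (micro-averaged) over folds — stable for small classes.
  The CV decision threshold is posterior ≥ 0.5; the 0.85 threshold belongs
  to the removal procedure only, where it judges sequences, not
  classifications.
* Windows truncated by a segment edge are dropped, not padded; an offset at
  which a class has fewer than `folds` windows ends the boundary scan.
* All randomness (fold shuffles, background-window placement, implant
  positions) derives from explicit seeds; one global seed derives
  per-stage seeds by string hashing, so every stage is independently
  reproducible and reruns serialize byte-identically.
* Degenerate inputs fail loudly: single-class training, all positives
  removed by purification, anchors whose seat window already scores below
  threshold (rejected as "no motif"), and empty anchor tables all produce
  distinct, informative conditions rather than silent results.

## Known limitations

* The anchor template is a literal-gap-literal regular expression; anchors
  with degenerate positions (e.g. Yxxφ) must be enumerated through the gap
  mechanism or larger alphabets, at combinatorial cost.
* Identity-based greedy clustering is quadratic in the number of sequences;
  for very large sets an external clusterer is the right tool.
* min(precision, recall) of the window classifier is the only motif
  quality; no E-value or significance calibration is attempted.
* At input purities near 10–20% the seat model is trained on a mostly
  background positive class, and purification removes some true carriers
  along with the contaminants — the same regime in which any
  classification-driven cleaning degrades.
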