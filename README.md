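# AnchorMotif

De novo discovery of **anchored protein sorting motifs** — signals built
from a short, highly conserved core (the twin-arginine `RR` of Tat signal
peptides, the `NPxY` of LDL-receptor tails) surrounded by a weakly
conserved flanking region — from a positive set of protein sequences that
share a sorting destination and a background set that does not. It is
designed for **impure positive sets**: an iterative false-positive-removal
procedure discards sequences unlikely to carry a true motif instance before
the motif is finalized, so discovery still works when only a minority of
the input actually carries the signal.

## Method in brief

Discovery is formulated as classification. For a candidate anchor `a`
(an instantiation of the gapped template
`<residues>{n} <gap>{min,max} <residues>{m}` found frequently in the
positive terminal segments), a two-class naive Bayes model over
width-`W` windows is trained: per class `c` and window column `j`, a
categorical residue distribution with Laplace smoothing,

    p̂_cj(i) = (n_cj(i) + α) / (N_cj + 20α),   α = 1 by default.

Positive windows are anchor-aligned; background windows come from negative
sequences (anchor-aligned when the negative contains the anchor, randomly
placed otherwise). Sliding the window outward from the anchor and
cross-validating at each offset locates the motif boundaries: extension
stops where the 5-fold min(precision, recall) drops below 0.5. The final
**motif score** is min(precision, recall) of the cross-validated classifier
on the boundary-delimited region — robust to class imbalance — and
conservation is summarized as Shannon **information content**,
`IC = Σ_j (log2 20 − H_j)` bits.

For impure inputs, `purifyPositives()` iterates: train at the anchor seat,
slide outward with retraining, track each sequence's window posteriors
until it accumulates 3 consecutive scores below 0.85, average each
sequence's pre-run scores, drop sequences below 0.85, and repeat until
stable (at most 10 rounds).

A synthetic benchmark generator (`generateBackground()`, `implantMotifs()`,
`runBenchmark()`) creates i.i.d.-background datasets with a 20-residue
implanted motif (anchor `AA`, hydrophobic or hydrophobic+charged flanks) at
controlled purity, with ground truth, so the whole pipeline is testable
without any downloads.

## Worked example

Build a half-pure synthetic dataset (120 positives, half of them carrying a
20-residue hydrophobic+charged implant; 120 i.i.d. background negatives)
and run discovery with false-positive removal:

```r
library(AnchorMotif)

pos <- generateBackground(120, 200, seed = 101, prefix = "pos")
imp <- implantMotifs(pos, implantSpec("hydrophobicCharged", trueRatio = 0.5),
                     seed = 102)
neg <- generateBackground(120, 200, seed = 103, prefix = "neg")
ds  <- SortingDataset(positive = imp$sequences, negative = neg)
ds
#> SortingDataset: 120 positive, 120 negative records (widths 200..200)

res <- discoverMotifs(ds, pipelineConfig(topK = 3, seed = 7))
head(res$anchors$N[, c("label", "support", "totalHits", "posFreq", "negFreq")], 3)
#>   label support totalHits   posFreq   negFreq
#> 1    AA     108       247 0.9000000 0.7166667
#> 2    LA     101       195 0.8416667 0.7000000
#> 3    AL     99        194 0.8250000 0.7583333

res$motifs[[1]]
#> MotifModel: anchor AA, length 20 (+8/+10 around the anchor)
#>   consensus xxxxxxxxAAxxxxxxxxxx
#>   motif score 0.880, information content 24.7 bits, 75 instances
```

Reading the output: the implanted anchor `AA` tops the frequency table
(90% positive support; its 72% background frequency is why anchor-matched
background windows are essential). After purification — 75 of the 120
positives survive, close to the 60 true carriers — the detected motif spans
20 residues around the anchor. The consensus is `x` at every flank position
(no single residue dominates; the flanks are conserved only in character),
yet the motif score of 0.88 shows the region separates carriers from
background far above chance, and the information content (24.7 bits versus
≈ 8.6 for the anchor alone) quantifies the flank conservation. Per-motif
PWMs can be exported with `writeMemeMotif()` for logo rendering.

Real data run the same way: `readFastaDataset()` for the two FASTA files,
`reduceRedundancy()` (80% identity) for preprocessing, or the thin
command-line wrapper:

```sh
Rscript inst/scripts/anchor-motif.R discover \
  --pos positives.fasta --neg background.fasta --end N --seed 1 --out out/
```

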