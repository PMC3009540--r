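Package: AnchorMotif
Title: De Novo Discovery of Anchored Protein Sorting Motifs from Impure Sequence Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers protein sorting signals composed of a short, highly
    conserved anchor (such as the twin-arginine RR or the NPxY internalization
    motif) surrounded by a weakly conserved flanking region. Frequent gapped
    anchors are enumerated in the terminal segments of a positive sequence set,
    a per-position categorical (naive Bayes) classifier scores fixed-width
    windows around each anchor against background sequences, motif boundaries
    are located by sliding-window cross-validation, and an iterative
    false-positive-removal procedure discards positive sequences unlikely to
    carry a true motif so that discovery still works when the positive set is
    impure. A synthetic implanted-motif benchmark generator is included for
    calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: SequenceMatching, MotifDiscovery, Classification, Proteomics
RoxygenNote: 7.3.3
Collate:
    'alphabet.R'
    'AnchorMotif-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'sequence-io.R'
    'anchor-search.R'
    'window-bayes.R'
    'fp-removal.R'
    'motif-model.R'
    'synth-bench.R'
    'pipeline.R'
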