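Package: dfim
Title: Deep Feature Interaction Maps for Regulatory Sequence Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates pairwise epistatic interactions between nucleotides
    and motifs in regulatory DNA sequences as learned by a trained
    sequence-to-activity neural network. A Feature Interaction Score (FIS)
    quantifies the change in a target feature's attribution when a source
    feature is perturbed in silico; per-sequence interaction maps, motif
    resolution scores with GC-background source mutation, cross-sequence
    aggregate maps, and a dinucleotide-shuffle empirical null with
    Benjamini-Hochberg correction are provided, together with a fully
    synthetic motif-interaction benchmark including a small trainable
    convolutional network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
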