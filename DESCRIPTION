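Package: scAccessNet
Title: Sequence-Based Single-Cell Chromatin Accessibility Modelling with a
    Probability-Sparse Transformer Encoder
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A unified framework for single-cell ATAC-seq analysis that
    predicts per-cell chromatin accessibility directly from peak DNA sequence
    with a probability-sparse self-attention Transformer encoder, and reuses
    the trained model for downstream analysis: the final linear layer's
    weights serve as cell embeddings for Louvain cell-type annotation; a
    per-peak, per-cluster Gamma-Normal mixture fitted by EM identifies likely
    dropout zeros which are recovered from model-predicted accessibility; and
    transcription factor activity is scored per cell by motif insertion into
    dinucleotide-shuffled backgrounds and per nucleotide by in-silico
    saturation mutagenesis. Includes a seeded synthetic scATAC-seq data
    generator with planted motifs so every stage can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    igraph
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: SingleCell, ATACSeq, Epigenetics, Sequencing, Transcription,
    MachineLearning, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
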