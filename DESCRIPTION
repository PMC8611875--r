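Package: hostnet
Title: Semi-Supervised Host Prediction for Prokaryotic Viruses from a
    Virus-Host Knowledge Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the taxonomic lineage (phylum to genus) of the
    prokaryotic host of query viruses. A knowledge graph connects viruses
    that share a significant number of protein clusters (hypergeometric
    test on Markov-clustered protein similarity networks) and connects
    viruses to candidate hosts by nucleotide alignment or known
    interaction. Node features come from a convolutional encoder over
    skip-gram k-mer embeddings; host nodes are encoded as
    alignment-weighted averages of their viral neighbours. One graph
    convolutional network per taxonomic rank is trained with a
    calibration-aware objective (expected calibration error plus mean
    squared error) so that SoftMax confidences can be thresholded, and
    cross-rank conflicts are resolved by truncating the reported lineage.
    Includes a synthetic community generator for end-to-end testing and
    supports extending the graph with hosts from taxa absent at training
    time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    data.table,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
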