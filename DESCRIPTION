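Package: duomics
Title: Integrated Transcriptome-Proteome Differential Expression, uORF and
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint analysis of a transcript-layer and a
    protein-layer abundance matrix from a two-condition experiment:
    empirical-Bayes moderated t differential expression with fold-change and
    FDR threshold classification, cross-layer concordance grouping of genes
    (up/up, up/unchanged, down/down), detection of upstream open reading
    frames (uORFs) in 5'UTR sequences with a Monte-Carlo carrier-enrichment
    test, right-sided hypergeometric term enrichment with Holm correction and
    kappa-score term grouping, and Markov-cluster (MCL) based deconstruction
    of interaction networks into functional cliques with first-neighbour
    reconstruction. A synthetic-data module generates all pipeline inputs
    with planted structure so the full workflow is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    fgsea,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
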