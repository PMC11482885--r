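Package: rnaclr
Title: Biologically Motivated Contrastive Pre-Training for Mature RNA
    Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-supervised representation learning for mature RNA
    sequences. Positive pairs are constructed from splice isoforms,
    orthologous transcripts (with a chimeric UTR transform for UTR-less
    orthologs) and random masking; transcripts are encoded as six-track
    matrices (nucleotide one-hot, splice-junction and codon-start
    indicators) and embedded with a selective state-space sequence
    encoder trained under a decoupled contrastive objective, optionally
    combined with masked language modelling. Includes annotation and
    sequence readers (genePred, BED12, FASTA), a synthetic gene-family
    corpus generator, linear probing with homology-aware splits,
    Z-score ablation statistics, and isoform functional-similarity
    analytics based on embedding distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    glmnet,
    jsonlite,
    yaml,
    withr,
    ape
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, MachineLearning, Sequencing, Software
RoxygenNote: 7.3.3
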