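Package: seqembed
Title: Dense k-mer Embeddings for 16S rRNA Amplicon Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trains skip-gram-with-negative-sampling (word2vec style) k-mer
    embeddings on a corpus of full-length 16S rRNA sequences and pools them
    into frequency-weighted, common-component-denoised embeddings of
    sequences, clusters, samples and body sites. Downstream tools cover
    pseudo-OTU generation by K-means in embedding space, centered log-ratio
    normalization, sparse multinomial (lasso) classification with balanced
    accuracy, clustering-fidelity metrics, alignment-based comparison
    analyses (pairwise identity, greedy clustering, consensus sequences),
    and activation-based traceback of the reads and k-mers that drive a
    classification. A synthetic-data module generates taxonomy-structured
    16S-like corpora, error-bearing reads and labeled samples so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    glmnet,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
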