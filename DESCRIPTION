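Package: mober
Title: Multi-Origin Batch Effect Removal with an Adversarial Conditional
    Variational Autoencoder
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates bulk RNA-seq count matrices from multiple origins
    (cell lines, xenografts, clinical tumor cohorts) into a shared latent
    embedding stripped of origin information, using a conditional
    variational autoencoder trained jointly with an adversarial source
    discriminator. Decoding a sample's latent code under a different
    one-hot source label projects its expression profile into another
    dataset's style, e.g. rendering a cell-line transcriptome as if it
    were a clinical tumor. Includes TMM/log-CPM preprocessing, projection
    based alignment evaluation (PCA + k-nearest-neighbor tumor-type
    assignment, batch-mixing entropy, differential expression), and a
    negative-binomial multi-source count simulator so the whole pipeline
    is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: BatchEffect, RNASeq, Transcriptomics, DimensionReduction
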