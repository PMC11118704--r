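Package: genophen
Title: Joint Masked-Language Modeling of Single-Cell Expression and Phenotype Tokens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multimodal masked-language-model framework for
    single-cell transcriptomics in which binned gene expression values and
    categorical phenotype labels (sex, age group, tissue, cell type) are
    encoded as one token sequence per cell and jointly reconstructed by a
    transformer encoder trained with a masked multi-task objective and
    ordinal soft labels. Provides expression preprocessing (library-size
    normalization, dispersion scaling, highly-variable-gene ranking,
    threshold detection and equal-width binning), vocabulary construction
    and cell tokenization, a pure-R transformer encoder with tied
    input/output embeddings and exact analytic gradients, Adam pretraining
    with linear warmup, masked-recovery evaluation (precision/recall/F1 and
    confusion matrices), phenotype annotation by mask filling, and an
    embedding-analysis toolkit: context-aggregated gene and phenotype
    embeddings, phenotype-gene similarity rankings, differentially embedded
    genes, tissue correlation dendrograms, similarity-threshold gene
    networks with discrete power-law degree-distribution fits,
    average-linkage gene dendrograms, and polyfunctionality clustering of
    per-cell gene embeddings. A seeded synthetic atlas generator with
    planted phenotype programs, a planted polyfunctional gene and an aged
    network variant makes the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mclust,
    Matrix,
    jsonlite,
    igraph,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
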