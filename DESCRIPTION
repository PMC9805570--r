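Package: moclust
Title: Joint Clustering of Paired Single-Cell Multi-Omics Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint clustering of paired single-cell multi-omics count data
    (CITE-seq RNA+protein, SNARE-seq RNA+ATAC). Each omics is modelled by a
    zero-inflated negative binomial (ZINB) or negative binomial autoencoder;
    per-omics latent representations are aligned across omics by a contrastive
    objective and fused with adaptively learned simplex weights; clustering is
    driven by a Cauchy-Schwarz divergence objective on the fused
    representation. A pretraining stage detects doublets automatically by
    synthesizing pseudo-doublets from cluster prototypes and thresholding
    assignment entropy at an empirical quantile. Includes readers for
    MatrixMarket, CSV and H5AD count matrices, ATAC peak-to-gene-activity
    conversion, a synthetic paired-omics generator with planted clusters and
    doublets, and NMI/ARI evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    rtracklayer,
    mclust,
    cluster,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
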