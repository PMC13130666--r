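Package: tumorstates
Title: Malignant Cell States, Copy-Number Inference, and Deconvolution
    Biomarkers in Tumor Single-Cell, Bulk, and Spatial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the tumor ecosystem around checkpoint
    immunotherapy from transcriptomic and multiplexed-imaging data.
    Implements expression-based copy-number aberration (CNA) inference with
    stromal reference adjustment, genetic subclone calling and
    malignant-cell classification; per-sample non-negative matrix
    factorization with cross-patient Jaccard metaclustering into
    metaprogram signatures; expression-bin-matched gene-signature scoring;
    stringent marker-rule gating of T-cell subsets with kNN rescue;
    pre/post-treatment composition statistics; bulk RNA-seq deconvolution
    with confounder-residual adjustment, purity-normalized malignant
    profiles and ROC evaluation of the malignant IFN/MHC-II biomarker; and
    CLR-normalized phenotype gating with radius-neighborhood statistics for
    segmented multiplexed-imaging cell tables. A synthetic-data generator
    with known ground truth (planted CNA blocks, subclones, expression
    programs, cell-type mixtures, and spatial neighborhood enrichments)
    makes the full pipeline testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    pracma,
    jsonlite,
    withr,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
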