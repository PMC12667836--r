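Package: striatlas
Title: Spatial and Multi-Omic Analysis of Striatal Cell-Type Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and testing cell-type atlases of the primate
    striatum from targeted spatial transcriptomics and single-nucleus
    multi-omic data. Implements reference-based per-cell decomposition with
    doublet-mode classification and two-round (major class, then MSN subtype)
    labeling; neighborhood-composition spatial niches for data-driven tissue
    demarcation; a spatial regression-discontinuity test for discrete
    cell-type boundaries, with Otsu boundary detection and nonlinear 1D
    spatial embeddings; rostro-caudal abundance-gradient statistics with
    LOESS smoothing and random-intercept mixed models; pseudobulk
    differential expression with empirical-Bayes moderation and a
    covariate-adaptive false discovery rate; negative-binomial outlier
    scoring for ATAC quality control; post-processing of cell-type by trait
    heritability-enrichment matrices; and a synthetic-data generator that
    produces spatial sections, reference panels, and rostro-caudal series
    with known ground truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    edgeR,
    limma,
    MASS,
    igraph,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
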