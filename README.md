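# striatlas

Spatial and multi-omic analysis of striatal cell-type atlases.

The primate striatum is dominated by medium spiny neurons (MSNs), whose
subtypes (D1/D2, striosome/matrix, ventral-striatum populations) occupy
distinct anatomical territories and gradients along the rostro-caudal
axis. Building a cell-type atlas from targeted spatial transcriptomics and
single-nucleus multi-omic data requires a chain of bespoke computations
that this package implements as tested, reusable functions:

- **Reference-based labeling** — per-cell decomposition over
  single-nucleus reference profiles by maximizing the Poisson profile
  likelihood $\sum_g y_g \log(\sum_t w_t p_{t,g})$ on the simplex, with
  platform-factor adjustment, singlet/doublet/rejected classification, the
  strict weight > 0.5 assignment rule, and two-round (major class →
  MSN subtype) labeling.
- **Spatial niches** — each cell summarized by the label composition of
  its k nearest neighbors, k-means clustered; the niche richest in MSNs
  demarcates the striatum.
- **Spatial regression discontinuity (RDD)** — tests whether a marker
  gene's expression jumps discretely at a spatial boundary or follows a
  continuous gradient: Otsu thresholding of the pooled axis coordinates
  finds the boundary $b$, and the Gaussian model
  $\mathrm{expr} = \beta_0 + \beta_1\,1[x > b] + \beta_2 (x - b)$
  tests the jump $\beta_1$ while controlling for the trend. Raw axes or a
  nonlinear 1D isomap embedding are supported.
- **Abundance gradients** — per-section type percentages, fold changes,
  SEM across sections, LOESS smoothing, and a random-intercept linear
  mixed model (REML) of percentage against rostro-caudal position with
  species as the random effect.
- **Pseudobulk differential expression** — cell-type × animal aggregation
  (≥ 15 cells), TMM + voom precision weights, weighted one-vs-all
  contrasts with empirical-Bayes variance moderation
  $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, simplified surrogate
  variables, and a covariate-adaptive FDR in which $\pi_0$ depends on
  average expression; pairwise DEG/OCR relatedness counts and cosine
  region similarity.
- **QC** — the strict RNA cell filter (nFeature in (2500, 10000),
  percent mito < 5) and two-round ATAC QC with a negative-binomial outlier
  model on fragment counts (|Pearson residual| > 2 excluded).
- **Enrichment post-processing** — jointly BH-adjusted signed
  −log10 FDR matrices over cell types × GWAS studies, double z-scoring
  with "+" calls, and a per-cell gene-set disease score with
  expression-matched control sets.
- **Synthetic data** — a generator producing reference panels, dissociated
  reference cells, spatial sections with territorial layouts, injected
  expression discontinuities, and rostro-caudal series with animal/species
  random effects — all with recorded ground truth, so every stage above is
  tested by recovery.

The central container is a `SingleCellExperiment` (genes × cells counts
plus spatial/stage metadata); reference panels, niche models and
enrichment matrices are S4 classes with accessors.

## Worked example

Simulate a two-type section with an injected expression discontinuity,
label the cells, and test the jump:

```r
library(striatlas)

bb <- list(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000)
cfg <- simulationConfig(seed = 2, nTypes = 2, nGenes = 24,
  territorySpec = list(
    list(types = "T1", density = 0.001,
         region = list(shape = "halfplane", axis = "x", side = "left",
                       at = 500, bbox = bb)),
    list(types = "T2", density = 0.001,
         region = list(shape = "halfplane", axis = "x", side = "right",
                       at = 500, bbox = bb))))
panel <- makeReference(cfg)
sec <- makeSection(panel, cfg, rcLevelMm = 0)
sec <- injectDiscontinuity(sec, "G015", "x", boundary = 500,
                           jump = 4, noiseSd = 0.5)

cts <- SummarizedExperiment::assay(sec, "counts")
W   <- decomposeCells(cts, panel)
sec$assigned_label <- assignLabel(W, classifyMode(cts, panel)$mode)$assigned_label
mean(sec$assigned_label == sec$true_type, na.rm = TRUE)
#> [1] 1

rddPipeline(sec, "G015", c("T1", "T2"), mode = "axis_x")
#>     gene boundary intercept  jumpBeta     slopeBeta     jumpSe       pValue
#> pos G015 500.7387  1.279504 0.4936177 -9.384046e-05 0.06977692 1.502854e-12
#>     nLeft nRight sectionId
#> pos   538    486      S1
```

The detected Otsu boundary (500.7 µm) falls on the injected divide; the
jump coefficient 0.49 is the injected step on the log1p-normalized scale,
and its Wald p-value (1.5e-12) reports a decisive discontinuity. Every
cell recovers its true label at the 0.5-weight threshold in this clean
two-type layout.

A full pipeline run (simulate → label → niche → rdd → gradients) from a
single config:

```r
runPipeline(system.file("extdata", "demo_config.yaml", package = "striatlas"),
            "demo_out")
```

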