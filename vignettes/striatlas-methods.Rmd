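---
title: "Methods: spatial and multi-omic analysis of striatal cell-type atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial and multi-omic analysis of striatal cell-type atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatlas)
```

# Overview

`striatlas` implements the computational core of a multimodal cell-type
atlas of the primate striatum: assigning cell-type labels to spatially
resolved cells from a single-nucleus reference, demarcating tissue by
neighborhood composition, testing whether marker-gene transitions across a
spatial axis are discrete or continuous, quantifying rostro-caudal
abundance gradients, calling differential expression from pseudobulk
replicates, scoring ATAC nuclei for quality, and post-processing cell-type
by trait heritability-enrichment matrices. A synthetic-data generator
produces every input with known ground truth, so each stage can be tested
end to end by recovery rather than by comparison with an irreproducible
dataset.

This vignette explains the models, their assumptions, the tunable
parameters and their defaults, and the design decisions taken where the
underlying procedure left choices open.

# The synthetic-data generator

The generator emulates a targeted spatial transcriptomics experiment on
coronal sections of macaque striatum, alongside an snRNA-seq-like
dissociated reference.

**Reference panel.** `makeReference()` builds cell-type profiles over a
gene panel: each type receives a disjoint block of marker genes elevated
`markerFold`-fold over a flat baseline, and rows are normalized to relative
expression summing to one. The defaults — 11 types over 366 genes — mirror
a targeted brain panel (a 266-gene base panel plus 100 custom genes)
queried against roughly a dozen medium-spiny-neuron (MSN) subtypes. The
deterministic construction makes marker identity and separation exact
ground truth; it deliberately omits the correlated, heavy-tailed expression
structure of real references, so recovery rates on synthetic data are
upper bounds for real data.

**Counts.** Per-cell library sizes are gamma-distributed with mean
`librarySizeMean` (default 200 transcripts, a realistic per-cell total for
a targeted panel) and squared coefficient of variation
`librarySizeDispersion` (default 0.25). Counts are negative binomial with
variance $\mu + \alpha\mu^2$ and $\alpha$ = `nbDispersion` = 0.1; setting
$\alpha = 0$ gives Poisson counts, which the tests use to check moment
behavior in the Poisson limit.

**Platform factors.** Spatial and dissociated assays capture genes with
different efficiencies. The generator multiplies each gene's expected rate
in spatial sections by a log-normal factor (sd `platformSd` = 0.3, drawn
once per configuration), then renormalizes each type's profile so depth is
preserved. No published quantification of these factors exists for this
assay pair; 0.3 gives 2-fold distortions for roughly a third of genes,
enough that decomposition without platform adjustment would degrade.

**Territories and gradients.** Sections place cells by a spatial Poisson
process within simple geometric territories (axis-aligned rectangles,
discs, half-planes). Real anatomical compartments — striosome islands, the
matrix background, medial-lateral ventral bands — are emulated by
composing these shapes; no image or segmentation structure is simulated.
Within a territory the type mix follows a multinomial-logit gradient: each
type's log-odds is `intercept + slope * rcIndex` plus per-animal and
per-species Gaussian intercepts drawn once per series. The gradient acts
on the logit scale so proportions stay in $(0,1)$; the mixed-model fit
converts to the percentage scale at analysis time. `rcIndex` is the rank
of the section's level in rostral-to-caudal order (0 = most rostral),
matching the ordinal coding used by the gradient test; rostro-caudal
position in mm from the anterior commissure is carried separately in the
cell metadata.

**Discontinuities.** `injectDiscontinuity()` overwrites one gene's counts
so its expected expression along a chosen axis is
$\beta_0 + \beta_2(x - b) + \beta_1 \mathbf{1}[x > b]$ plus Gaussian rate
noise, realized as negative-binomial counts, with the true jump stored in
the object metadata. Injection targets should be baseline (non-marker)
genes: overwriting a marker gene changes the affected cells' total counts
and thereby induces a spurious depth discontinuity in every *other* gene's
normalized expression — an instructive artifact, but not the intended
null.

# Reference-based labeling

**Decomposition.** Each cell's counts are modeled as a Poisson sample from
a convex mixture of platform-adjusted reference profiles. With profiles
normalized per type, the weight vector maximizes the multinomial profile
likelihood $\sum_g y_g \log (\sum_t w_t p_{t,g})$ on the simplex, fitted by
EM multiplicative updates from a uniform start (tolerance $10^{-8}$ on the
largest weight change, at most 1000 iterations; cells are frozen
individually as they converge). EM guarantees monotone likelihood ascent,
which the test suite asserts per iteration, and the fit matches an
exhaustive simplex grid search at step 0.01 within 0.02 on small
instances. This is a simplification of full robust decomposition: the
Poisson likelihood omits gene-specific variance inflation, which is
adequate at panel scale (hundreds of genes, hundreds of counts).

**Platform factors.** `estimatePlatformFactors()` compares depth-normalized
spatial and reference pseudobulks gene by gene. The ratio is additively
smoothed (pseudo-count 0.5 per gene) so low-count ratios shrink toward 1
while genuine per-gene shifts are preserved, clamped to $[0.05, 20]$;
genes absent from either pseudobulk fall back to 1.

**Doublet modes.** `classifyMode()` compares the best single-type
log-likelihood with the best two-type mixture, searching pairs among each
cell's top three singlet candidates (a tractability choice; with well
separated profiles the best pair virtually always involves the top
singlets). Improvement below `llMargin` (10 nats) is a singlet; at least
twice the margin with both weights above 0.25 is a certain doublet;
anything between is uncertain. Independently, a cell is **rejected** when
the mean per-count log-likelihood of its best fitted model falls more than
`rejectSd` (default 6) standard deviations below that model's own
expectation, using exact multinomial moments at the cell's depth — a
closed-form version of calibrating against matched-depth simulations.
Six standard deviations keeps false rejection of genuine cells negligible
while uniform-noise cells at typical depths sit tens of deviations below
the floor. The floor is evaluated against the best *fitted* model (singlet
or pair), not the best singlet, so genuine doublets are not rejected.

**Assignment.** A cell is labeled with the type whose weight strictly
exceeds 0.5; otherwise it is `UNCLASSIFIED`; rejected cells are excluded
from labeled output. Ties at exactly 0.5 do not assign. Labeling is
two-round: major classes first, then MSN-labeled cells are re-decomposed
against the subtype panel. The summary reports the MSN fraction of cells
and of neurons for comparison with real-data expectations.

# Spatial niches and demarcation

Each cell is described by the label composition of its $k$ nearest labeled
neighbors (default $k = 30$; Euclidean distance; self excluded; ties broken
deterministically by distance then cell order; exact brute-force search in
blocks). Unlabeled cells contribute to nobody's composition but receive
one. Compositions are clustered by k-means (Lloyd, 10 restarts, fixed
seed, default 30 niches, matching the clustering scale of the niche
assay), and the striatal mask is the single niche with the highest MSN
proportion.

A single-niche mask can cover a territory only if that territory is
compositionally tight at the label level used: k-means will split a region
whose neighbor compositions vary (e.g. a striatum containing a substantial
mixed population) across several niches, each of which would then be
MSN-rich. The demarcation demonstration therefore uses a major-class
labeling in which the striatal block is MSN-homogeneous and is separated
from the mixed cortical block by a cell-free, white-matter-like gap —
conditions under which the mask covers the striatum almost exactly. On
real data the practical remedy is either merging MSN-rich niches or
lowering the label resolution, which the function supports through its
`msnLabels` argument.

# Spatial regression discontinuity

The question is whether a marker gene's expression changes *abruptly* at a
spatial boundary between two related cell types, or merely follows a
continuous gradient — discrete transitions support distinct types rather
than cell states.

**Axis.** The spatial axis is either a raw coordinate or a nonlinear 1D
isomap embedding: a symmetric k-nearest-neighbor graph on $(x, y)$, graph
shortest-path distances, and the first classical-MDS coordinate, with the
sign fixed to correlate positively with $x$. Sections beyond 2000 cells
are embedded through a seeded landmark subsample, and remaining cells
inherit their nearest landmark's coordinate. A disconnected graph raises
an error suggesting a larger neighborhood.

**Boundary.** `otsuBoundary()` histograms the pooled axis coordinates of
the two compared types into 128 bins and scans every interior bin edge for
the maximal between-class variance $\omega_0\omega_1(\mu_0-\mu_1)^2$ —
an exhaustive scan, with ties broken toward the median coordinate. Using
the pooled coordinate histogram (rather than expression-weighted
coordinates) reflects that the bimodal spatial occupancy of the two
populations is what defines the boundary; the alternative inputs remain
possible by passing any coordinate vector.

**Test.** With the axis centered at the boundary, the Gaussian working
model
$$\mathrm{expr} = \beta_0 + \beta_1 \mathbf{1}[x > 0] + \beta_2 x +
\varepsilon$$
is fitted by least squares, and $\beta_1$ is tested with a two-sided Wald
test against a normal reference, exactly the Gaussian GLM form; the null
model is the linear-only fit. No side-specific slope is included by
default (`separateSlopes` adds the interaction). Expression enters as
log1p depth-normalized counts — the Gaussian model presumes a roughly
homoskedastic normalized scale. Degenerate noiseless fits use the
convention $p = 1$ for a zero jump and $p = 0$ otherwise; both sides must
hold at least 20 cells. Sections are always tested separately and never
pooled across animals.

Calibration was checked by simulation: on null linear gradients the
rejection rate at $\alpha = 0.05$ over 1000 sections of 1000 cells stays
within $[0.03, 0.07]$, and a jump of one noise standard deviation with 500
cells per side is detected with power above 0.9.

# Gradients and the mixed model

`abundanceGradient()` aggregates labeled cells per section into
percentages within a declared label group, computes the fold change
between a declared pair (guarding zero denominators), and reports the
standard error of the mean across sections within each rostro-caudal
level. `loessSmooth()` provides display smoothing: local linear fits with
tricube weights over the `span` fraction of nearest points — exact on
globally linear signals at any span, falling back to a local weighted mean
on degenerate designs.

`lmmFit()` implements the gradient test: a Gaussian random-intercept model
of per-section percentage against the rostro-caudal ordinal index with
species (or animal) as the grouping factor, fitted by direct REML profile
likelihood over the variance ratio $\lambda = \sigma^2_b/\sigma^2_e$
(block-diagonal algebra, 1D optimization with an explicit boundary check
at $\lambda = 0$). With a single group, or at the boundary, the slope
equals the ordinary least-squares slope exactly. Wald inference uses a t
reference with residual degrees of freedom; simulation at the study's
scale (two species, five levels, slope 1.44) shows about 95 percent
confidence-interval coverage. The section index rather than mm distance is
used as the fixed effect because sampled levels are unevenly spaced;
`lme4` agrees with the fits to numerical accuracy in the test suite.

One compositional caveat the simulations make explicit: percentages within
a group sum to 100, so a genuinely rising type mechanically depresses every
other type's percentage. A "flat" type holds a stable percentage only when
gains and losses elsewhere balance (as when a matrix type expands at the
expense of striosome types); the end-to-end tests construct exactly that
balanced exchange.

# Pseudobulk differential expression

Cells are summed into cell-type-by-animal pseudobulk aggregates;
aggregates under 15 cells are excluded, and each aggregate's gene
detection rate is kept as a technical covariate. Normalization and
precision weights are delegated to the standard tools: TMM scale factors
(`edgeR::calcNormFactors`) and observation-level plus sample-quality
weights (`limma::voomWithQualityWeights`). The reported `scaleFactors`
are effective library scales (library size times TMM factor, geometric
mean 1), so a uniformly doubled sample shows a factor of 2.

The moderated fit itself is implemented in the package. Per gene, a
weighted least-squares model on `~ 0 + cellType + nCells + detectionRate`
(covariates standardized; constant covariates dropped) is extended with
surrogate variables — principal components of the residual matrix after
regressing out the design, their number chosen by permutation parallel
analysis (95th percentile of permuted singular values), capped at 5 — a
deliberate simplification of iterative surrogate-variable analysis.
One-vs-all contrasts give per-type log fold changes. Variances are
moderated by
$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g},$$
with $(d_0, s_0^2)$ estimated by method of moments on $\log s^2_g$ using a
Newton inversion of the trigamma function; $d_0 = 0$ recovers the ordinary
t and $d_0 = \infty$ a pooled z, both asserted numerically against
independent references (`t.test`, `limma::lmFit`). Intra-animal
correlation is approximated by the animal-level aggregation itself rather
than a consensus-correlation step; this is a documented simplification.

**Covariate-adaptive FDR.** The null proportion is allowed to depend on
average expression: $\pi_0(x)$ is estimated by regressing
$\mathbf{1}[p > \lambda]$ on the covariate with a linear basis, averaged
over $\lambda \in \{0.5, 0.6, 0.7, 0.8\}$, clamped to $[0.01, 1]$, and
q-values are $\pi_0(x_g)$ times the BH adjustment. With a constant
covariate this reduces exactly to scalar-$\pi_0$ q-values. Adjustment
within each cell type gives `adjPWithin`; pooling all cell types first
gives the more conservative `adjPBetween`. Simulations with signal
concentrated at high covariate values show more discoveries than plain BH
(guaranteed pointwise, since $\pi_0 \le 1$) with empirical FDR holding at
the nominal level.

**Relatedness counts.** The number of significantly upregulated features
between each ordered pair of types serves as a relatedness measure (fewer
differences, more similar). Expression pairs run through the pseudobulk
moderated pipeline; accessibility-style comparisons use a per-feature
rank-sum test at single-cell level (normal approximation with tie
correction, verified against exhaustive pair enumeration) under the rule
FDR $\le 0.05$ and log2 fold change $\ge 0.25$. Rank tests on
depth-normalized sparse counts are sensitive to systematic depth
differences between populations — normalization makes every gene's values
a near-deterministic function of cell depth at low counts — so planted
two-population fixtures must keep expected depths exchangeable, as the
test suite's symmetric designs do.

`cosineRegionSimilarity()` down-samples nuclei per region (default 500),
computes cosine similarities between all sampled nuclei pairs in PCA space
of log-normalized expression, averages within region pairs, and orders
regions by average-linkage clustering.

# ATAC quality control

RNA-side cell filters are the printed rule applied with strict
inequalities: more than 2500 and fewer than 10000 detected genes, and
mitochondrial percentage below 5.

ATAC QC is two-round. Round 1 removes nuclei with fewer than $10^{3.5}$
fragments (and accepts an upstream doublet flag as a precomputed column —
the doublet simulation itself is out of scope). Round 2 fits the negative
binomial regression `glm.nb(nFrags ~ TSSEnrichment + PromoterRatio +
DoubletEnrichment)` and excludes nuclei whose standardized residual
exceeds 2 in absolute value, with the Pearson scale
$(y - \mu)/\sqrt{\mu + \mu^2/\theta}$ as the default standardization
(a deviance-scale option and a one-sided mode are provided, since the
published wording does not pin either down). Coefficient recovery,
Poisson-limit agreement with a Poisson GLM, and agreement of the flagged
fraction with the model-implied $P(|r| > 2)$ are all verified by
simulation.

# Enrichment post-processing

Association p-values for cell type-study pairs (e.g. 11 MSN subtypes by
121 GWAS) are BH-adjusted over the *entire* grid jointly, and the signed
score is the coefficient sign times $-\log_{10}$ adjusted p. The "+"
calling then z-scores the significant scores twice — per study across cell
types, and within each cell type by trait-category bin — and calls a pair
when both z-scores exceed 1 and the pair is significant. Z-scores are
computed over significant entries only by default (the full-matrix mode is
a flag), bins of size one or zero variance yield z = 0, and calls are
invariant to reordering studies within a category. The signed score (not
its absolute value) enters the z-scores by default.

The per-cell gene-set score is a simplified disease-relevance score:
expression is residualized per gene on log total counts and log detected
features, the observed score is the mean residual over the gene set, and
its z-score is taken against control sets matched exactly to the set's
mean-expression-bin histogram (default 200 control sets, 25 bins; bins
smaller than their quota sample with replacement and are flagged). The
upstream gene scoring that produces the set itself is out of scope; any
gene list can be supplied.

# Problem sizes, determinism, and limitations

All simulations in the test suite and the acceptance script are sized for
a desk-scale run: sections of one to a few thousand cells, series of
twenty sections, 200-1000 Monte Carlo replicates per calibration check,
and a 50,000-coordinate layout for boundary-detection accuracy. These
sizes were chosen so each check's Monte Carlo error is small relative to
its acceptance margin.

Every generator function draws from a seed substream derived by hashing a
stage or section tag with the configuration seed, so identical
configurations are bit-identical regardless of what else ran, and
inserting a pipeline stage does not perturb other stages' draws. The
pipeline writes a manifest (parameters, seed, output checksums) per stage.

Known limitations: profiles are independent across genes (no co-expression
modules); platform factors are gene-wise multiplicative only; the
decomposition ignores NB overdispersion in its likelihood; the niche
demarcation returns a single niche as the mask; the surrogate-variable and
sample-correlation steps are simplified relative to their full iterative
counterparts; and passing recovery tests on this generator demonstrates
correctness of the implementations, not performance on tissue with
segmentation errors, ambient contamination, or doublet structure the
generator does not emulate.
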