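#' @import methods
#' @importFrom stats cmdscale approx coef cor cor.test cutree dist dnbinom dnorm dpois
#'   hclust kmeans lm lm.wfit loess lowess mad median model.matrix optimize
#'   p.adjust pchisq pnbinom pnorm power prcomp predict pt qnorm qt quantile
#'   rbinom resid rgamma rlnorm rmultinom rnbinom rnorm rpois runif sd setNames
#'   var wilcox.test
#' @importFrom stats digamma psigamma trigamma
#' @importFrom utils combn head read.delim write.table
#' @importFrom tools md5sum
NULL

#' Reference expression panel
#'
#' Cell-type by gene mean expression profiles used as the reference for
#' per-cell decomposition. Each row of \code{mu} is a cell type's expected
#' relative expression over the panel genes and sums to one. \code{panelMask}
#' marks the genes present on the targeted spatial panel and
#' \code{markerMap} records, per type, the genes that are elevated in that
#' type (its marker block).
#'
#' @slot geneIds character vector of gene identifiers (columns of \code{mu}).
#' @slot typeIds character vector of cell-type identifiers (rows of \code{mu}).
#' @slot mu numeric matrix, types x genes, nonnegative, rows summing to 1.
#' @slot panelMask logical vector over genes; TRUE for genes on the panel.
#' @slot markerMap named list mapping type id to its marker gene ids.
#'
#' @seealso [makeReference()], [decomposeCell()]
#' @exportClass ReferencePanel
setClass("ReferencePanel",
  representation(
    geneIds = "character",
    typeIds = "character",
    mu = "matrix",
    panelMask = "logical",
    markerMap = "list"
  )
)

setValidity("ReferencePanel", function(object) {
  msgs <- character()
  G <- length(object@geneIds)
  T <- length(object@typeIds)
  if (!all(dim(object@mu) == c(T, G)))
    msgs <- c(msgs, "mu must be typeIds x geneIds")
  if (any(object@mu < 0))
    msgs <- c(msgs, "mu entries must be nonnegative")
  if (any(abs(rowSums(object@mu) - 1) > 1e-9))
    msgs <- c(msgs, "each row of mu must sum to 1 within 1e-9")
  if (length(object@panelMask) != G)
    msgs <- c(msgs, "panelMask must have one entry per gene")
  if (!all(unlist(object@markerMap) %in% object@geneIds))
    msgs <- c(msgs, "marker genes must belong to geneIds")
  onPanel <- object@geneIds[object@panelMask]
  nOn <- vapply(object@markerMap, function(m) sum(m %in% onPanel), 0L)
  if (length(object@markerMap) && any(nOn < 2))
    msgs <- c(msgs, "panelMask must retain >= 2 marker genes per type")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", length(object@typeIds), "types x",
      length(object@geneIds), "genes;",
      sum(object@panelMask), "genes on spatial panel\n")
  cat("  types:", paste(head(object@typeIds, 6), collapse = ", "),
      if (length(object@typeIds) > 6) "..." else "", "\n")
})

#' @describeIn ReferencePanel gene identifiers
#' @param x a \code{ReferencePanel}
#' @export
geneIds <- function(x) x@geneIds

#' @describeIn ReferencePanel cell-type identifiers
#' @export
typeIds <- function(x) x@typeIds

#' @describeIn ReferencePanel the types x genes profile matrix
#' @export
profileMatrix <- function(x) {
  m <- x@mu
  dimnames(m) <- list(x@typeIds, x@geneIds)
  m
}

#' @describeIn ReferencePanel marker genes for one type (or all, as a list)
#' @param type optional type id
#' @export
markerGenes <- function(x, type = NULL) {
  if (is.null(type)) x@markerMap else x@markerMap[[type]]
}

#' Simulation configuration
#'
#' Holds every tunable of the synthetic-data generator: panel size, count
#' model, spatial territories, rostro-caudal abundance gradients, and
#' expression discontinuities. The seed is recorded and echoed into all
#' outputs so that identical configurations reproduce bit-identical tables.
#'
#' @slot seed integer RNG seed.
#' @slot nTypes,nGenes panel dimensions.
#' @slot markerFold fold elevation of a type's marker genes over baseline.
#' @slot markersPerType number of (disjoint) marker genes per type.
#' @slot librarySizeMean mean transcripts per cell.
#' @slot librarySizeDispersion squared coefficient of variation of per-cell
#'   library size (gamma-distributed); 0 gives a fixed library size.
#' @slot nbDispersion per-count negative-binomial overdispersion alpha, with
#'   variance mu + alpha * mu^2; 0 gives Poisson counts.
#' @slot platformSd sd of per-gene log-normal platform factors applied to
#'   spatial (but not reference) counts.
#' @slot territorySpec list of territories, each
#'   \code{list(types=, region=, density=)}; see [makeSection()].
#' @slot gradientSpec data.frame with columns \code{type}, \code{intercept},
#'   \code{slope} (per rostro-caudal unit, logit scale), \code{animalSd},
#'   \code{speciesSd}.
#' @slot discontinuitySpec list of \code{list(gene=, axis=, boundary=, jump=,
#'   slope=, noiseSd=)} applied by [injectDiscontinuity()].
#'
#' @seealso [simulationConfig()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nTypes = "integer",
    nGenes = "integer",
    markerFold = "numeric",
    markersPerType = "integer",
    librarySizeMean = "numeric",
    librarySizeDispersion = "numeric",
    nbDispersion = "numeric",
    platformSd = "numeric",
    territorySpec = "list",
    gradientSpec = "data.frame",
    discontinuitySpec = "list"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nTypes < 2L) msgs <- c(msgs, "nTypes must be >= 2")
  if (object@nGenes < 2L * object@nTypes)
    msgs <- c(msgs, "nGenes must be >= 2 * nTypes")
  if (object@librarySizeMean <= 0) msgs <- c(msgs, "librarySizeMean must be > 0")
  if (object@nbDispersion < 0) msgs <- c(msgs, "nbDispersion must be >= 0")
  dens <- vapply(object@territorySpec, function(t) t$density, 0)
  if (length(dens) && any(dens < 0)) msgs <- c(msgs, "densities must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults emulate the study conditions of a macaque-striatum targeted
#' spatial panel: 11 MSN-like subtypes over a 366-gene panel (a 266-gene
#' base panel plus 100 custom genes), a mean per-cell depth of 200
#' transcripts, negative-binomial counts with dispersion 0.1, and per-gene
#' log-normal platform factors with sd 0.3.
#'
#' @param seed integer seed.
#' @param nTypes,nGenes,markerFold,markersPerType panel structure.
#' @param librarySizeMean,librarySizeDispersion,nbDispersion,platformSd
#'   count model; see \linkS4class{SimulationConfig}.
#' @param territorySpec,gradientSpec,discontinuitySpec spatial structure;
#'   see \linkS4class{SimulationConfig}.
#' @return a \linkS4class{SimulationConfig}
#' @examples
#' cfg <- simulationConfig(seed = 1, nTypes = 3, nGenes = 30)
#' @export
simulationConfig <- function(seed = 1L,
                             nTypes = 11L,
                             nGenes = 366L,
                             markerFold = 10,
                             markersPerType = NULL,
                             librarySizeMean = 200,
                             librarySizeDispersion = 0.25,
                             nbDispersion = 0.1,
                             platformSd = 0.3,
                             territorySpec = list(),
                             gradientSpec = NULL,
                             discontinuitySpec = list()) {
  nTypes <- as.integer(nTypes); nGenes <- as.integer(nGenes)
  if (is.null(markersPerType))
    markersPerType <- max(2L, as.integer(nGenes %/% (2L * nTypes)))
  if (is.null(gradientSpec))
    gradientSpec <- data.frame(
      type = paste0("T", seq_len(nTypes)),
      intercept = 0, slope = 0, animalSd = 0, speciesSd = 0,
      stringsAsFactors = FALSE)
  new("SimulationConfig",
      seed = as.integer(seed), nTypes = nTypes, nGenes = nGenes,
      markerFold = markerFold, markersPerType = as.integer(markersPerType),
      librarySizeMean = librarySizeMean,
      librarySizeDispersion = librarySizeDispersion,
      nbDispersion = nbDispersion, platformSd = platformSd,
      territorySpec = territorySpec, gradientSpec = gradientSpec,
      discontinuitySpec = discontinuitySpec)
}

#' Spatial niche model
#'
#' Result of the neighborhood-composition niche assay: the cells x labels
#' neighbor-composition matrix, the k-means niche assignment per cell, the
#' niche with the highest MSN proportion (the striatal niche), and the
#' k-means centroids.
#'
#' @slot kNeighbors neighbors per cell used for the composition.
#' @slot nClusters requested number of niches.
#' @slot composition integer matrix, cells x labels; rows sum to kNeighbors.
#' @slot nicheOfCell integer niche id per cell.
#' @slot striatalNiche id of the niche maximizing the MSN proportion.
#' @slot centroids k-means centroids (niches x labels).
#' @slot msnLabels labels counted as MSN when ranking niches.
#' @seealso [neighborhoodComposition()], [clusterNiches()]
#' @exportClass NicheModel
setClass("NicheModel",
  representation(
    kNeighbors = "integer",
    nClusters = "integer",
    composition = "matrix",
    nicheOfCell = "integer",
    striatalNiche = "integer",
    centroids = "matrix",
    msnLabels = "character"
  )
)

setMethod("show", "NicheModel", function(object) {
  cat("NicheModel:", nrow(object@composition), "cells,",
      object@nClusters, "niches (k =", object@kNeighbors, "neighbors)\n")
  cat("  striatal niche:", object@striatalNiche, "(",
      sum(object@nicheOfCell == object@striatalNiche), "cells )\n")
})

#' @describeIn NicheModel logical mask of cells in the striatal niche
#' @param x a \code{NicheModel}
#' @export
striatumMask <- function(x) x@nicheOfCell == x@striatalNiche

#' @describeIn NicheModel niche id per cell
#' @export
nicheOfCell <- function(x) x@nicheOfCell

#' Cell-type by study enrichment matrix
#'
#' Post-processed heritability-enrichment results: jointly BH-adjusted
#' p-values over the full cell type x study grid, signed -log10 adjusted
#' p scores, the study-to-trait-category map, the two z-score layers
#' (within study across cell types; within cell type and trait category),
#' and the resulting "+" calls.
#'
#' @slot pValues,signs,adjP,signedScore numeric matrices, cell types x studies.
#' @slot categoryMap named character: study id -> trait category.
#' @slot zWithinStudy,zWithinCellTypeBin numeric matrices (NA where undefined).
#' @slot plusCall logical matrix of "+" calls.
#' @slot alpha significance level used for the calls.
#' @seealso [signedLogFdrMatrix()], [doubleZscorePlus()]
#' @exportClass EnrichmentMatrix
setClass("EnrichmentMatrix",
  representation(
    pValues = "matrix",
    signs = "matrix",
    adjP = "matrix",
    signedScore = "matrix",
    categoryMap = "character",
    zWithinStudy = "matrix",
    zWithinCellTypeBin = "matrix",
    plusCall = "matrix",
    alpha = "numeric"
  )
)

setMethod("show", "EnrichmentMatrix", function(object) {
  cat("EnrichmentMatrix:", nrow(object@pValues), "cell types x",
      ncol(object@pValues), "studies\n")
  if (length(object@plusCall))
    cat("  '+' calls:", sum(object@plusCall, na.rm = TRUE), "\n")
})

#' @describeIn EnrichmentMatrix signed -log10 adjusted p-value matrix
#' @param x an \code{EnrichmentMatrix}
#' @export
signedScores <- function(x) x@signedScore

#' @describeIn EnrichmentMatrix logical matrix of "+" calls
#' @export
plusCalls <- function(x) x@plusCall
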