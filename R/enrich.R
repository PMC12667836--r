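## Post-processing of cell-type x study association matrices: joint BH
## adjustment, signed -log10 scores, the double z-scoring that produces
## "+" calls, and a per-cell gene-set disease-relevance score with
## expression-matched control gene sets.

#' Signed -log10 FDR matrix
#'
#' Benjamini-Hochberg adjustment over the flattened cell type x study grid
#' (all pairs jointly, e.g. 11 cell types x 121 studies), then
#' \code{signedScore = sign x (-log10 adjP)}. NaN p-values are excluded
#' from the BH family and stay NA in the output.
#'
#' @param pMatrix cell types x studies matrix of association p-values
#' @param signMatrix matching matrix of coefficient signs (-1 / +1)
#' @param categoryMap named character vector, study -> trait category
#'   (optional here, required for [doubleZscorePlus()])
#' @param alpha significance level recorded for downstream calls
#' @return an \linkS4class{EnrichmentMatrix}
#' @export
signedLogFdrMatrix <- function(pMatrix, signMatrix, categoryMap = character(),
                               alpha = 0.05) {
  stopifnot2(all(dim(pMatrix) == dim(signMatrix)),
             "p and sign matrices must match")
  ok <- is.finite(pMatrix)
  stopifnot2(all(pMatrix[ok] >= 0 & pMatrix[ok] <= 1),
             "p-values must lie in [0, 1]")
  stopifnot2(all(signMatrix[ok] %in% c(-1, 1)), "signs must be -1 or +1")
  adj <- matrix(NA_real_, nrow(pMatrix), ncol(pMatrix),
                dimnames = dimnames(pMatrix))
  adj[ok] <- p.adjust(pMatrix[ok], method = "BH")
  score <- signMatrix * (-log10(adj))
  new("EnrichmentMatrix", pValues = pMatrix, signs = signMatrix, adjP = adj,
      signedScore = score, categoryMap = categoryMap,
      zWithinStudy = matrix(NA_real_, 0, 0),
      zWithinCellTypeBin = matrix(NA_real_, 0, 0),
      plusCall = matrix(FALSE, 0, 0), alpha = alpha)
}

## z-score a vector; bins of size 1 or zero variance give z = 0.
.safeZ <- function(v) {
  ok <- is.finite(v)
  if (sum(ok) <= 1) { v[ok] <- 0; return(v) }
  s <- sd(v[ok])
  if (s == 0) { v[ok] <- 0; return(v) }
  (v - mean(v[ok])) / s
}

#' Double z-scoring and "+" calls
#'
#' Identifies cell type-trait pairs standing out in both directions of the
#' enrichment matrix: scores are z-scored per study across cell types
#' (within-study z), then binned by cell type and major trait category and
#' z-scored within each bin (within-cell-type z). A "+" is called when both
#' z-scores exceed 1 and the pair is significant at \code{alpha}. By
#' default the z-scores are computed over the significant signed scores
#' only (\code{significantOnly = FALSE} uses the full matrix). Degenerate
#' bins (size 1 or zero variance) get z = 0.
#'
#' @param enr an \linkS4class{EnrichmentMatrix} with a category map covering
#'   all studies
#' @param alpha significance level for the calls
#' @param significantOnly restrict the z-score mean/sd to significant pairs
#' @return the \linkS4class{EnrichmentMatrix} with z-score slots and
#'   \code{plusCall} filled
#' @export
doubleZscorePlus <- function(enr, alpha = enr@alpha, significantOnly = TRUE) {
  score <- enr@signedScore
  studies <- colnames(score)
  stopifnot2(all(studies %in% names(enr@categoryMap)),
             "categoryMap must cover all studies")
  sig <- is.finite(enr@adjP) & enr@adjP <= alpha
  base <- score
  if (significantOnly) base[!sig] <- NA
  z1 <- apply(base, 2, .safeZ)
  dimnames(z1) <- dimnames(score)
  z2 <- matrix(NA_real_, nrow(score), ncol(score), dimnames = dimnames(score))
  cats <- enr@categoryMap[studies]
  for (ct in seq_len(nrow(score))) for (cat in unique(cats)) {
    cols <- which(cats == cat)
    z2[ct, cols] <- .safeZ(base[ct, cols])
  }
  plus <- !is.na(z1) & !is.na(z2) & z1 > 1 & z2 > 1 & sig
  methods::initialize(enr, zWithinStudy = z1, zWithinCellTypeBin = z2,
                      plusCall = plus, alpha = alpha)
}

## Control gene sets matched to a gene set's expression-bin histogram: for
## every bin the set occupies, sample the same number of genes from that
## bin (with replacement, flagged, when the bin is too small).
.matchedControlSets <- function(setBins, byBin, nControls) {
  need <- table(setBins)
  flagged <- character()
  sets <- lapply(seq_len(nControls), function(i) {
    unlist(lapply(names(need), function(b) {
      pool <- byBin[[b]]
      k <- need[[b]]
      if (length(pool) < k) {
        flagged <<- union(flagged, b)
        sample(pool, k, replace = TRUE)
      } else pool[sample.int(length(pool), k)]
    }), use.names = FALSE)
  })
  attr(sets, "flagged") <- flagged
  sets
}

#' Per-cell gene-set score with matched controls
#'
#' The aggregated expression of a gene set (e.g. the top putative disease
#' genes of a trait) per cell, compared against control gene sets matched
#' by mean-expression bin: expression is first residualized on the per-cell
#' covariates (log total counts and log features detected), the observed
#' score is the mean residual over the set, and each control set samples,
#' per set gene, a random gene from the same mean-expression bin — so the
#' controls' bin histogram equals the set's exactly. The z-score is
#' (observed - control mean) / control sd.
#'
#' @param expr genes x cells normalized expression matrix
#' @param geneSet character vector of gene ids (at least 10 must be
#'   measured)
#' @param nControls number of control sets (default 200)
#' @param nBins mean-expression bins for matching (default 25)
#' @param totalCounts,nFeatures per-cell covariates (defaults derived from
#'   \code{expr} when NULL)
#' @param seed RNG seed for control sampling
#' @return data.frame per cell: \code{observed}, \code{controlMean},
#'   \code{controlSd}, \code{z}; attribute \code{flagged} lists bins where
#'   controls were sampled with replacement
#' @export
geneSetCellScore <- function(expr, geneSet, nControls = 200, nBins = 25,
                             totalCounts = NULL, nFeatures = NULL, seed = 1) {
  expr <- as.matrix(expr)
  geneSet <- intersect(geneSet, rownames(expr))
  stopifnot2(length(geneSet) >= 10,
             "need >= 10 measured genes in the gene set")
  if (is.null(totalCounts)) totalCounts <- colSums(expr)
  if (is.null(nFeatures)) nFeatures <- colSums(expr > 0)
  ## residualize every gene on the covariates (OLS, shared design)
  X <- cbind(1, log1p(totalCounts), log1p(nFeatures))
  qrX <- qr(X)
  R <- t(expr) - X %*% qr.coef(qrX, t(expr))
  R[is.na(R)] <- 0                       # constant covariate columns
  meanExpr <- rowMeans(expr)
  bins <- cut(rank(meanExpr, ties.method = "first"), breaks = nBins,
              labels = FALSE)
  binOf <- setNames(bins, rownames(expr))
  byBin <- split(rownames(expr), bins)
  setBins <- binOf[geneSet]
  observed <- rowMeans(R[, geneSet, drop = FALSE])
  sets <- withSeed(seed, .matchedControlSets(setBins, byBin, nControls))
  flagged <- attr(sets, "flagged")
  ctl <- vapply(sets, function(picks) rowMeans(R[, picks, drop = FALSE]),
                numeric(ncol(expr)))
  cm <- rowMeans(ctl)
  cs <- apply(ctl, 1, sd)
  out <- data.frame(observed = observed, controlMean = cm, controlSd = cs,
                    z = ifelse(cs > 0, (observed - cm) / cs, NA_real_),
                    row.names = colnames(expr))
  attr(out, "flagged") <- flagged
  out
}
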