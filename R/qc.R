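## Quality control: rule-based RNA cell filters and the two-round ATAC QC
## with negative-binomial outlier scoring of fragment counts.

#' Rule-based RNA cell filter
#'
#' A cell passes when \code{nFeature > 2500}, \code{nFeature < 10000} and
#' \code{percentMito < 5} — all inequalities strict, exactly as the filter
#' is defined. Cells at a boundary (e.g. nFeature = 2500 or percent
#' mitochondrial = 5.0) fail.
#'
#' @param nFeature genes detected per cell
#' @param percentMito mitochondrial percentage per cell
#' @param minFeature,maxFeature,maxMito thresholds
#' @return list: \code{pass} (logical per cell) and \code{summary}
#' @export
rnaQcFilter <- function(nFeature, percentMito, minFeature = 2500,
                        maxFeature = 10000, maxMito = 5) {
  stopifnot2(!anyNA(nFeature) && !anyNA(percentMito),
             "nFeature and percentMito must be available for every cell")
  pass <- nFeature > minFeature & nFeature < maxFeature & percentMito < maxMito
  list(pass = pass,
       summary = list(nCells = length(pass), nPass = sum(pass),
                      nFailFeature = sum(!(nFeature > minFeature &
                                             nFeature < maxFeature)),
                      nFailMito = sum(!(percentMito < maxMito))))
}

#' Two-round ATAC QC with NB outlier scoring
#'
#' Round 1 discards cells with fewer than \eqn{10^{3.5}} fragments (and,
#' when supplied, cells flagged as doublets upstream). Round 2 fits a
#' negative-binomial regression of fragment count on TSS enrichment,
#' promoter ratio and doublet enrichment
#' (\code{glm.nb(nFrags ~ TSSEnrichment + PromoterRatio +
#' DoubletEnrichment)}), standardizes the residuals on the Pearson scale
#' \eqn{(y - \mu) / \sqrt{\mu + \mu^2/\theta}}, and excludes cells with
#' absolute residual above \code{residualCutoff} (two-sided by default;
#' \code{oneSided = TRUE} flags only high outliers).
#'
#' @param qc data.frame with columns \code{nFrags}, \code{TSSEnrichment},
#'   \code{PromoterRatio}, \code{DoubletEnrichment}, and optionally
#'   \code{doubletPass} (logical round-1 doublet filter)
#' @param residualCutoff residual threshold (default 2)
#' @param minFrags round-1 fragment floor (default \code{10^3.5})
#' @param oneSided flag only positive residuals
#' @param scale residual scale, \code{"pearson"} (default) or
#'   \code{"deviance"}
#' @param formula model formula (override for reduced models, e.g.
#'   \code{nFrags ~ 1})
#' @return list: \code{qc} (input plus \code{round1Pass},
#'   \code{residual}, \code{round2Pass}), \code{fit} (coefficients with
#'   standard errors, \code{theta}, convergence), \code{summary}
#' @export
nbOutlierFlags <- function(qc, residualCutoff = 2, minFrags = 10^3.5,
                           oneSided = FALSE, scale = c("pearson", "deviance"),
                           formula = nFrags ~ TSSEnrichment + PromoterRatio +
                             DoubletEnrichment) {
  scale <- match.arg(scale)
  need <- c("nFrags", "TSSEnrichment", "PromoterRatio", "DoubletEnrichment")
  stopifnot2(all(need %in% names(qc)), "missing QC columns")
  round1 <- qc$nFrags >= minFrags
  if (!is.null(qc$doubletPass)) round1 <- round1 & qc$doubletPass
  d <- qc[round1, , drop = FALSE]
  stopifnot2(nrow(d) >= 40, "need >= 10x more cells than coefficients")
  fit <- suppressWarnings(
    MASS::glm.nb(formula, data = d,
                 control = stats::glm.control(maxit = 100, epsilon = 1e-8)))
  mu <- stats::fitted(fit)
  theta <- fit$theta
  r <- if (scale == "pearson") (d$nFrags - mu) / sqrt(mu + mu^2 / theta)
       else stats::residuals(fit, type = "deviance")
  flag <- if (oneSided) r > residualCutoff else abs(r) > residualCutoff
  qc$round1Pass <- round1
  qc$residual <- NA_real_
  qc$residual[round1] <- r
  qc$round2Pass <- FALSE
  qc$round2Pass[round1] <- !flag
  thetaHigh <- theta > 1e5
  if (thetaHigh)
    warning("dispersion at upper bound; counts effectively Poisson")
  list(qc = qc,
       fit = list(coefficients = coef(fit),
                  se = suppressWarnings(summary(fit)$coefficients[, 2]),
                  theta = theta, mu = mu,
                  converged = fit$converged, thetaHigh = thetaHigh),
       summary = list(nCells = nrow(qc), nRound1Fail = sum(!round1),
                      nOutliers = sum(flag),
                      nPass = sum(qc$round2Pass)))
}

#' Model-implied outlier probability
#'
#' For a fitted NB QC model, the probability that a cell's standardized
#' residual exceeds the cutoff in absolute value under the fitted model —
#' the expected flagged fraction when the model is correctly specified.
#'
#' @param mu fitted means
#' @param theta fitted NB dispersion parameter
#' @param cutoff residual cutoff
#' @return per-cell probabilities
#' @export
nbOutlierProbability <- function(mu, theta, cutoff = 2) {
  sdv <- sqrt(mu + mu^2 / theta)
  lo <- mu - cutoff * sdv
  hi <- mu + cutoff * sdv
  pLow <- ifelse(lo > 0, pnbinom(ceiling(lo) - 1, mu = mu, size = theta), 0)
  pHigh <- 1 - pnbinom(floor(hi), mu = mu, size = theta)
  pLow + pHigh
}
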