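## Abundance gradients along the rostro-caudal axis: reference-correlation
## checks, per-section percentage summaries with fold changes and SEM,
## LOESS smoothing, and the random-intercept mixed-model gradient test.

#' Correlation between spatial cells and the reference, per type
#'
#' For each labeled type, correlates the log1p depth-normalized mean
#' expression of the type's spatial cells with the reference profile over
#' the shared panel genes (Pearson), reporting r-squared and the
#' correlation-test p-value. High correlation indicates the type is truly
#' present in the section; types with too few cells or zero-variance
#' vectors are flagged.
#'
#' @param cells a labeled SpatialCellTable
#' @param panel a \linkS4class{ReferencePanel}
#' @param labelCol colData column holding labels
#' @param minCells minimum cells per type (default 20)
#' @param scale depth-normalization scale (counts per \code{scale})
#' @return data.frame: \code{type}, \code{nCells}, \code{r}, \code{r2},
#'   \code{pValue}, \code{flag}
#' @export
referenceCorrelation <- function(cells, panel, labelCol = "assigned_label",
                                 minCells = 20, scale = 100) {
  labels <- SummarizedExperiment::colData(cells)[[labelCol]]
  shared <- intersect(rownames(cells), panel@geneIds)
  stopifnot2(length(shared) >= 3, "need >= 3 shared panel genes")
  cts <- SummarizedExperiment::assay(cells, "counts")[shared, , drop = FALSE]
  depth <- pmax(Matrix::colSums(SummarizedExperiment::assay(cells, "counts")), 1)
  norm <- Matrix::t(Matrix::t(cts) / depth) * scale
  ref <- profileMatrix(panel)[, shared, drop = FALSE] * scale
  out <- lapply(panel@typeIds, function(t) {
    idx <- which(!is.na(labels) & labels == t)
    if (length(idx) < minCells)
      return(data.frame(type = t, nCells = length(idx), r = NA, r2 = NA,
                        pValue = NA, flag = "too_few_cells"))
    m <- log1p(Matrix::rowMeans(norm[, idx, drop = FALSE]))
    rv <- log1p(ref[t, ])
    if (sd(m) == 0 || sd(rv) == 0)
      return(data.frame(type = t, nCells = length(idx), r = NA, r2 = NA,
                        pValue = NA, flag = "zero_variance"))
    ct <- cor.test(m, rv)
    data.frame(type = t, nCells = length(idx), r = unname(ct$estimate),
               r2 = unname(ct$estimate)^2, pValue = ct$p.value, flag = "ok")
  })
  do.call(rbind, out)
}

#' Per-section abundance percentages, fold change, and SEM
#'
#' Within a declared label group (e.g. the VS subtypes), computes for every
#' section the percentage of each type (100 x count / group total), the
#' fold change between a declared type pair (percent B over percent A), and
#' the standard error of the mean of each type's percentage across sections
#' within each rostro-caudal level. Sections with an empty group, or fold
#' changes with a zero denominator, are flagged rather than dropped.
#'
#' @param cells a labeled SpatialCellTable (or a list of them, combined)
#' @param group character vector of labels forming the group
#' @param pair optional \code{c(typeA, typeB)} for the fold change B/A
#' @param labelCol colData column holding labels
#' @return list with \code{perSection} (section, rc_level_mm, type, count,
#'   percent), \code{foldChange} (per section, flagged when undefined) and
#'   \code{sem} (rc level x type SEM across sections)
#' @export
abundanceGradient <- function(cells, group, pair = NULL,
                              labelCol = "assigned_label") {
  if (is.list(cells) && !methods::is(cells, "SingleCellExperiment")) {
    cd <- do.call(rbind, lapply(cells, function(s)
      as.data.frame(SummarizedExperiment::colData(s))))
  } else {
    cd <- as.data.frame(SummarizedExperiment::colData(cells))
  }
  lab <- cd[[labelCol]]
  keep <- !is.na(lab) & lab %in% group
  cd <- cd[keep, , drop = FALSE]; lab <- lab[keep]
  secs <- split(seq_len(nrow(cd)), cd$section_id)
  perSection <- do.call(rbind, lapply(names(secs), function(s) {
    idx <- secs[[s]]
    counts <- table(factor(lab[idx], levels = group))
    tot <- sum(counts)
    data.frame(section_id = s, rc_level_mm = cd$rc_level_mm[idx[1]],
               type = group, count = as.integer(counts),
               percent = if (tot > 0) 100 * as.numeric(counts) / tot
                         else NA_real_,
               flag = if (tot > 0) "ok" else "empty_group",
               stringsAsFactors = FALSE)
  }))
  foldChange <- NULL
  if (!is.null(pair)) {
    stopifnot2(length(pair) == 2 && all(pair %in% group),
               "pair must name two group labels")
    foldChange <- do.call(rbind, lapply(split(perSection,
                                              perSection$section_id),
      function(d) {
        a <- d$percent[d$type == pair[1]]; b <- d$percent[d$type == pair[2]]
        data.frame(section_id = d$section_id[1],
                   rc_level_mm = d$rc_level_mm[1],
                   foldChange = if (!is.na(a) && a > 0) b / a else NA_real_,
                   flag = if (is.na(a) || a == 0) "zero_denominator" else "ok",
                   stringsAsFactors = FALSE)
      }))
    rownames(foldChange) <- NULL
  }
  sem <- do.call(rbind, lapply(split(perSection,
                                     list(perSection$rc_level_mm,
                                          perSection$type), drop = TRUE),
    function(d) data.frame(rc_level_mm = d$rc_level_mm[1], type = d$type[1],
                           nSections = nrow(d), meanPercent = mean(d$percent),
                           sem = if (nrow(d) > 1)
                                   sd(d$percent) / sqrt(nrow(d))
                                 else NA_real_)))
  rownames(sem) <- NULL
  list(perSection = perSection, foldChange = foldChange, sem = sem)
}

#' LOESS smoothing (tricube local linear regression)
#'
#' Local linear regression: each query point is fitted by weighted least
#' squares over the \code{ceiling(span * n)} nearest points in x, with
#' tricube weights on the scaled distance. A globally linear signal is
#' reproduced exactly at any span; a degenerate local design (all
#' neighbors at one x) falls back to the local weighted mean.
#'
#' @param x,y data points
#' @param span fraction of points in each local neighborhood, in (0, 1]
#' @param xout query points (default: \code{x})
#' @return fitted values at \code{xout}
#' @export
loessSmooth <- function(x, y, span = 0.75, xout = x) {
  n <- length(x)
  stopifnot2(n >= 3, "need >= 3 points")
  stopifnot2(span > 0 && span <= 1, "span must be in (0, 1]")
  q <- max(2L, ceiling(span * n))
  vapply(xout, function(x0) {
    d <- abs(x - x0)
    nb <- order(d, seq_len(n))[seq_len(q)]
    dmax <- max(d[nb])
    w <- if (dmax == 0) rep(1, q) else (1 - pmin(d[nb] / dmax, 1)^3)^3
    w[w <= 0] <- 1e-12
    xs <- x[nb]
    if (max(xs) - min(xs) < 1e-12 * max(1, abs(x0)))
      return(sum(w * y[nb]) / sum(w))
    fit <- lm.wfit(cbind(1, xs - x0), y[nb], w)
    fit$coefficients[1]
  }, 0)
}

#' Random-intercept linear mixed model by REML
#'
#' Fits \eqn{y = \beta_0 + \beta_1 x + b_{group} + \epsilon} with Gaussian
#' random intercepts, by direct REML profile-likelihood optimization over
#' the variance ratio \eqn{\lambda = \sigma^2_b / \sigma^2_e}. With a single
#' group (or a boundary estimate \eqn{\lambda = 0}) the slope equals the
#' ordinary least-squares slope. Inference on the slope is a Wald t-test
#' with residual degrees of freedom. Used for the rostro-caudal gradient
#' test: per-section type percentage against the section's rostro-caudal
#' index, with species (or animal) as the grouping factor.
#'
#' @param y response (e.g. per-section percentages)
#' @param x fixed covariate (e.g. rostro-caudal ordinal index)
#' @param group grouping factor for the random intercept
#' @return list: \code{beta}, \code{seBeta}, \code{pValue},
#'   \code{intercept}, \code{randomInterceptSd}, \code{residualSd},
#'   \code{nObs}, \code{nGroups}, \code{boundary} (TRUE if the variance
#'   ratio was estimated at 0), \code{logRestrictedLik}
#' @export
lmmFit <- function(y, x, group) {
  n <- length(y)
  stopifnot2(n >= 2, "need >= 2 observations")
  group <- as.factor(group)
  X <- cbind(1, x)
  p <- ncol(X)
  idx <- split(seq_len(n), group)
  nG <- length(idx)

  ## GLS pieces for V = I + lambda * Z Z' (block diagonal per group):
  ## V_i^{-1} = I - lambda/(1 + lambda n_i) J_i, via group sums.
  glsFit <- function(lambda) {
    XtVX <- matrix(0, p, p); XtVy <- numeric(p)
    yVy <- 0; logDetV <- 0
    for (ig in idx) {
      Xi <- X[ig, , drop = FALSE]; yi <- y[ig]; ni <- length(ig)
      c1 <- lambda / (1 + lambda * ni)
      sx <- colSums(Xi); sy <- sum(yi)
      XtVX <- XtVX + crossprod(Xi) - c1 * tcrossprod(sx)
      XtVy <- XtVy + crossprod(Xi, yi) - c1 * sx * sy
      yVy <- yVy + sum(yi^2) - c1 * sy^2
      logDetV <- logDetV + log1p(lambda * ni)
    }
    beta <- solve(XtVX, XtVy)
    rss <- as.numeric(yVy - crossprod(XtVy, beta))  # (y-Xb)' V^-1 (y-Xb)
    sigma2 <- rss / (n - p)                          # REML scale
    ## restricted log-likelihood (up to an additive constant)
    ll <- -0.5 * (logDetV + (n - p) * log(rss) +
                    determinant(XtVX, logarithm = TRUE)$modulus)
    list(beta = beta, sigma2 = sigma2, XtVX = XtVX, ll = as.numeric(ll))
  }

  if (nG == 1) {
    lambda <- 0
  } else {
    obj <- function(loglam) -glsFit(exp(loglam))$ll
    opt <- optimize(obj, c(-12, 12))
    lambda <- exp(opt$minimum)
    if (-obj(log(1e-12)) >= -opt$objective) lambda <- 0   # boundary check
  }
  fit <- glsFit(lambda)
  covBeta <- fit$sigma2 * solve(fit$XtVX)
  se <- sqrt(diag(covBeta))
  df <- n - p
  tval <- fit$beta[2] / se[2]
  list(beta = unname(fit$beta[2]), seBeta = unname(se[2]),
       pValue = 2 * pt(-abs(tval), df),
       intercept = unname(fit$beta[1]),
       randomInterceptSd = sqrt(lambda * fit$sigma2),
       residualSd = sqrt(fit$sigma2),
       nObs = n, nGroups = nG, boundary = lambda == 0,
       df = df, logRestrictedLik = fit$ll)
}

#' Rostro-caudal gradient test for one type
#'
#' Computes per-section percentages of \code{type} within \code{group} (via
#' [abundanceGradient()]) and fits [lmmFit()] of percentage against the
#' rostro-caudal ordinal index (0 = most rostral section level, increasing
#' caudally) with a random intercept per \code{groupingCol} (default
#' species).
#'
#' @param sections list of labeled SpatialCellTables
#' @param type type whose gradient is tested
#' @param group label group defining the denominator
#' @param labelCol colData column holding labels
#' @param groupingCol metadata column used as the random-intercept factor
#' @return the [lmmFit()] result plus the per-section table used
#' @export
gradientTest <- function(sections, type, group,
                         labelCol = "assigned_label",
                         groupingCol = "species_id") {
  ag <- abundanceGradient(sections, group, labelCol = labelCol)
  ps <- ag$perSection[ag$perSection$type == type &
                        ag$perSection$flag == "ok", , drop = FALSE]
  meta <- do.call(rbind, lapply(sections, function(s) {
    cd <- SummarizedExperiment::colData(s)
    data.frame(section_id = cd$section_id[1], grp = cd[[groupingCol]][1],
               stringsAsFactors = FALSE)
  }))
  ps$grp <- meta$grp[match(ps$section_id, meta$section_id)]
  lev <- sort(unique(ps$rc_level_mm), decreasing = TRUE)
  ps$rcIndex <- match(ps$rc_level_mm, lev) - 1
  fit <- lmmFit(ps$percent, ps$rcIndex, ps$grp)
  fit$perSection <- ps
  fit
}
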