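## Pseudobulk differential expression: aggregation, TMM + precision-weight
## normalization (edgeR/limma), weighted linear models with one-vs-all
## contrasts and empirical-Bayes variance moderation, a covariate-adaptive
## FDR, pairwise relatedness counts, and cosine region similarity.

#' Aggregate cells into (cell type, animal) pseudobulks
#'
#' Sums raw counts per cell type x animal combination. Aggregates with
#' fewer than \code{minCells} cells are excluded (and listed); the gene
#' detection rate (fraction of genes with count > 0) is recorded per
#' aggregate for use as a technical covariate.
#'
#' @param counts genes x cells count matrix
#' @param labels cell-type label per cell (NA / UNCLASSIFIED dropped)
#' @param animals animal id per cell
#' @param minCells minimum cells per aggregate (default 15)
#' @return list: \code{counts} (genes x aggregates), \code{meta}
#'   (cellType, animal, nCells, detectionRate), \code{excluded}
#' @export
aggregatePseudobulk <- function(counts, labels, animals, minCells = 15) {
  keep <- !is.na(labels) & labels != UNCLASSIFIED
  counts <- methods::as(counts, "CsparseMatrix")[, keep, drop = FALSE]
  grp <- factor(paste(labels[keep], animals[keep], sep = "||"))
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp), x = 1,
                              dims = c(length(grp), nlevels(grp)))
  agg <- as.matrix(counts %*% ind)
  nCells <- as.integer(table(grp))
  parts <- do.call(rbind, strsplit(levels(grp), "||", fixed = TRUE))
  meta <- data.frame(cellType = parts[, 1], animal = parts[, 2],
                     nCells = nCells,
                     detectionRate = colMeans(agg > 0),
                     stringsAsFactors = FALSE)
  ok <- meta$nCells >= minCells
  stopifnot2(any(ok), "no aggregate survives the minimum-cell filter")
  colnames(agg) <- paste(meta$cellType, meta$animal, sep = ".")
  rownames(agg) <- rownames(counts)
  list(counts = agg[, ok, drop = FALSE], meta = meta[ok, , drop = FALSE],
       excluded = meta[!ok, , drop = FALSE])
}

#' Normalize pseudobulks and estimate precision weights
#'
#' Filters low-count genes (CPM > \code{minCpm} in at least
#' \code{minSamples} aggregates) and ribosomal/mitochondrial genes by
#' symbol prefix, computes TMM scale factors
#' (\code{edgeR::calcNormFactors}), and estimates observation-level
#' precision weights from the mean-variance trend together with
#' sample-specific quality weights (\code{limma::voomWithQualityWeights}).
#'
#' @param pb result of [aggregatePseudobulk()]
#' @param design optional design matrix (default: one column per cell type)
#' @param minCpm,minSamples low-count filter
#' @param dropPrefixes regular expressions of gene symbols to exclude
#' @return list: \code{E} (log2-CPM), \code{weights} (combined observation
#'   x sample weights), \code{sampleWeights}, \code{normFactors} (TMM),
#'   \code{scaleFactors} (effective library scale: library size x TMM
#'   factor, normalized to geometric mean 1), \code{meta}, \code{keptGenes}
#' @export
normalizeAndWeight <- function(pb, design = NULL, minCpm = 1, minSamples = 2,
                               dropPrefixes = c("^RP[SL]", "^MRP[SL]", "^MT-")) {
  cts <- pb$counts
  stopifnot2(ncol(cts) >= 2, "need >= 2 aggregates")
  stopifnot2(all(colSums(cts) > 0), "an aggregate has all-zero counts")
  drop <- Reduce(`|`, lapply(dropPrefixes, grepl, x = rownames(cts)),
                 accumulate = FALSE)
  cts <- cts[!drop, , drop = FALSE]
  cpm <- t(t(cts) / colSums(cts)) * 1e6
  keep <- rowSums(cpm > minCpm) >= min(minSamples, ncol(cts))
  cts <- cts[keep, , drop = FALSE]
  stopifnot2(nrow(cts) > 0, "no gene passes the low-count filter")
  if (is.null(design)) {
    ct <- factor(pb$meta$cellType)
    design <- if (nlevels(ct) > 1) model.matrix(~ 0 + ct)
              else matrix(1, ncol(cts), 1)
  }
  dge <- edgeR::DGEList(counts = cts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  v <- limma::voomWithQualityWeights(dge, design = design, plot = FALSE)
  sw <- v$targets$sample.weights
  if (is.null(sw)) sw <- attr(v$weights, "arrayweights")
  ## effective scale factor: library size x TMM factor, geometric mean 1
  eff <- dge$samples$lib.size * dge$samples$norm.factors
  scaleFactors <- eff / exp(mean(log(eff)))
  list(E = v$E, weights = v$weights, sampleWeights = sw,
       normFactors = dge$samples$norm.factors, scaleFactors = scaleFactors,
       meta = pb$meta, keptGenes = rownames(cts))
}

## Newton inversion of the trigamma function (for d0 estimation).
.trigammaInverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance moderation
#'
#' The shrinkage formula applied to each gene's variance:
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}
#' \code{d0 = 0} returns the gene variance unchanged (ordinary t);
#' \code{d0 = Inf} returns the prior variance (pooled z).
#'
#' @param s2 gene residual variance
#' @param df gene residual degrees of freedom
#' @param d0 prior degrees of freedom
#' @param s02 prior variance
#' @return the moderated variance
#' @export
moderatedVariance <- function(s2, df, d0, s02) {
  if (is.infinite(d0)) return(rep_len(s02, length(s2)))
  (d0 * s02 + df * s2) / (d0 + df)
}

## Method-of-moments fit of the scaled inverse-chi-square prior for the
## gene variances on the log scale: returns d0 (prior df, possibly Inf)
## and s02 (prior variance).
.fitVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = exp(emean)))
  d0 <- 2 * .trigammaInverse(evar)
  if (!is.finite(d0)) return(list(d0 = Inf, s02 = exp(emean)))
  list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

## Weighted least-squares fit of one design across all genes.
## Returns per-gene coefficients, unscaled covariance factors for the
## requested contrasts, residual variances and degrees of freedom.
.weightedFits <- function(E, W, X, contrasts) {
  G <- nrow(E); p <- ncol(X); nC <- ncol(contrasts)
  est <- matrix(NA_real_, G, nC); uvar <- matrix(NA_real_, G, nC)
  s2 <- numeric(G)
  df <- nrow(X) - p
  stopifnot2(df > 0, "no residual degrees of freedom")
  for (g in seq_len(G)) {
    w <- W[g, ]
    fit <- lm.wfit(X, E[g, ], w)
    Ci <- chol2inv(chol(crossprod(X * sqrt(w))))
    b <- fit$coefficients
    s2[g] <- sum(w * fit$residuals^2) / df
    est[g, ] <- drop(t(b) %*% contrasts)
    uvar[g, ] <- colSums(contrasts * (Ci %*% contrasts))
  }
  list(est = est, uvar = uvar, s2 = s2, df = rep(df, G))
}

## Simplified surrogate-variable estimation: principal components of the
## residual matrix after regressing out the full design, with the number of
## components chosen by permutation parallel analysis (95th percentile of
## permuted singular values), capped at maxSv.
.estimateSv <- function(E, X, maxSv = 5, nPerm = 10, seed = 1) {
  H <- X %*% solve(crossprod(X), t(X))
  R <- E - E %*% t(H)
  sv <- svd(R, nu = 0, nv = maxSv)
  permD <- withSeed(seed, {
    replicate(nPerm, {
      Rp <- t(apply(R, 1, sample))
      svd(Rp, nu = 0, nv = 0)$d[seq_len(maxSv)]
    })
  })
  thr <- apply(permD, 1, quantile, probs = 0.95)
  nSv <- sum(sv$d[seq_len(maxSv)] > thr)
  if (nSv == 0) return(NULL)
  sv$v[, seq_len(nSv), drop = FALSE]
}

#' Moderated one-vs-all differential expression
#'
#' Fits a weighted linear model per gene on the design \code{~ 0 + cellType
#' + nCells + detectionRate} (plus surrogate variables: residual principal
#' components chosen by permutation parallel analysis, capped at 5), forms
#' one-vs-all contrasts per cell type, and moderates the gene variances
#' with the empirical-Bayes shrinkage
#' \deqn{\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g)}
#' where \eqn{(d_0, s_0^2)} are estimated by method of moments on
#' \eqn{\log s^2_g}. Moderated t-statistics are referred to a t
#' distribution on \eqn{d_g + d_0} df (\eqn{d_0 = \infty} gives a normal
#' reference with the pooled variance). P-values are adjusted by the
#' covariate-adaptive FDR within each cell type
#' (\code{adjPWithin}) and across all cell types pooled
#' (\code{adjPBetween}, the more conservative scheme).
#'
#' @param norm result of [normalizeAndWeight()]
#' @param nSv \code{"auto"} (permutation choice), or an integer count
#' @param d0,s02 optional overrides of the prior (forcing \code{d0 = 0}
#'   gives the ordinary t; \code{d0 = Inf} the pooled z)
#' @param covariates character: technical covariate columns of the
#'   aggregate metadata to include
#' @return list: \code{table} (gene, contrast, log2FC, t, pValue,
#'   adjPWithin, adjPBetween, aveExpr), \code{d0}, \code{s02}, \code{nSv}
#' @export
fitModerated <- function(norm, nSv = "auto", d0 = NULL, s02 = NULL,
                         covariates = c("nCells", "detectionRate")) {
  E <- norm$E; W <- norm$weights; meta <- norm$meta
  ct <- factor(meta$cellType)
  stopifnot2(nlevels(ct) >= 2, "need >= 2 cell types for one-vs-all contrasts")
  X <- model.matrix(~ 0 + ct)
  colnames(X) <- levels(ct)
  for (cv in covariates) {
    v <- meta[[cv]]
    if (!is.null(v) && sd(v) > 0) X <- cbind(X, scale(v)[, 1])
  }
  SV <- NULL
  if (identical(nSv, "auto")) {
    SV <- .estimateSv(E, X)
  } else if (is.numeric(nSv) && nSv > 0) {
    H <- X %*% solve(crossprod(X), t(X))
    R <- E - E %*% t(H)
    SV <- svd(R, nu = 0, nv = nSv)$v
  }
  if (!is.null(SV)) X <- cbind(X, SV)
  stopifnot2(qr(X)$rank == ncol(X), "design is rank deficient")
  Tn <- nlevels(ct)
  L <- matrix(0, ncol(X), Tn, dimnames = list(colnames(X), levels(ct)))
  for (t in seq_len(Tn)) {
    L[t, t] <- 1
    L[setdiff(seq_len(Tn), t), t] <- -1 / (Tn - 1)
  }
  fits <- .weightedFits(E, W, X, L)
  if (is.null(d0) || is.null(s02)) {
    prior <- .fitVariancePrior(fits$s2, fits$df)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  }
  if (is.na(d0) || d0 < 0) {
    warning("prior df estimate failed; falling back to pooled variance")
    d0 <- Inf
  }
  s2tilde <- moderatedVariance(fits$s2, fits$df, d0, s02)
  tstat <- fits$est / sqrt(fits$uvar * s2tilde)
  dfTotal <- fits$df + d0
  pval <- if (is.infinite(d0)) 2 * pnorm(-abs(tstat)) else
    2 * pt(-abs(tstat), dfTotal)
  aveExpr <- rowMeans(E)
  tab <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    data.frame(gene = rownames(E), contrast = levels(ct)[t],
               log2FC = fits$est[, t], t = tstat[, t], pValue = pval[, t],
               aveExpr = aveExpr, stringsAsFactors = FALSE)
  }))
  tab$adjPWithin <- NA_real_
  for (ctr in unique(tab$contrast)) {
    i <- tab$contrast == ctr
    tab$adjPWithin[i] <- adaptiveFdr(tab$pValue[i], tab$aveExpr[i])
  }
  tab$adjPBetween <- adaptiveFdr(tab$pValue, tab$aveExpr)
  rownames(tab) <- NULL
  list(table = tab, d0 = d0, s02 = s02,
       nSv = if (is.null(SV)) 0L else ncol(SV))
}

#' Covariate-adaptive false discovery rate
#'
#' Estimates the local null proportion \eqn{\pi_0(x)} by regressing the
#' indicator \eqn{1[p > \lambda]} on the covariate (linear basis), averaged
#' over a grid of \eqn{\lambda} values and clamped to \eqn{[0.01, 1]}, and
#' returns \eqn{q_g = \pi_0(x_g) \times} the BH-adjusted p-value. With a
#' constant (or missing) covariate this reduces to scalar-\eqn{\pi_0}
#' q-values. Pooling p-values across cell types before adjustment gives the
#' "between" scheme; adjusting per cell type gives the "within" scheme.
#'
#' @param p p-values in [0, 1]
#' @param covariate per-test covariate (e.g. average gene expression)
#' @param lambdaGrid thresholds averaged over for the \eqn{\pi_0} fit
#' @param pi0 optional fixed null proportion, bypassing estimation
#'   (\code{pi0 = 1} gives plain BH adjustment)
#' @return q-values, same length as \code{p}
#' @export
adaptiveFdr <- function(p, covariate = NULL,
                        lambdaGrid = c(0.5, 0.6, 0.7, 0.8), pi0 = NULL) {
  stopifnot2(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  bh <- p.adjust(p, method = "BH")
  n <- length(p)
  if (!is.null(pi0)) return(pmin(pi0 * bh, 1))
  if (is.null(covariate) || sd(covariate) == 0) {
    pi0 <- mean(vapply(lambdaGrid,
                       function(l) mean(p > l) / (1 - l), 0))
    pi0 <- min(max(pi0, 0.01), 1)
    return(pmin(pi0 * bh, 1))
  }
  stopifnot2(all(is.finite(covariate)), "covariate must be finite")
  X <- cbind(1, covariate)
  fits <- vapply(lambdaGrid, function(l) {
    ind <- as.numeric(p > l)
    drop(X %*% qr.coef(qr(X), ind)) / (1 - l)
  }, numeric(n))
  pi0x <- pmin(pmax(rowMeans(fits), 0.01), 1)
  pmin(pi0x * bh, 1)
}

## Vectorized two-group rank-sum test (normal approximation with tie
## correction) across the rows of a matrix.
.rankSumRows <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  sub <- x[, c(g1, g2), drop = FALSE]
  stats <- apply(sub, 1, function(v) {
    r <- rank(v)
    R1 <- sum(r[seq_len(n1)])
    U <- R1 - n1 * (n1 + 1) / 2
    ties <- table(v)
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- n1 * n2 / 12 * ((N + 1) - tieCorr)
    c(U = U, z = if (sig2 > 0) (U - n1 * n2 / 2) / sqrt(sig2) else 0)
  })
  list(U = stats["U", ], z = stats["z", ],
       p = 2 * pnorm(-abs(stats["z", ])))
}

#' Pairwise relatedness counts
#'
#' For every ordered pair of labels, counts the features significantly
#' upregulated in the first label versus the second — the count of DEGs (or
#' differential open-chromatin regions) used as a proxy for relatedness,
#' with fewer differences indicating more similar types.
#' \code{mode = "moderated_t"} runs the pseudobulk moderated pipeline per
#' pair (requires \code{animals}; pairs where a label has fewer than 2
#' aggregates are skipped and flagged); \code{mode = "wilcoxon"} runs a
#' per-feature rank-sum test at single-cell level (normal approximation
#' with tie correction) with the accessibility-style rule FDR <= alpha and
#' log2FC >= lfcMin.
#'
#' @param x features x cells matrix: raw counts for \code{moderated_t}
#'   (pseudobulked internally), normalized values for \code{wilcoxon}
#' @param labels label per cell
#' @param mode test mode
#' @param animals animal per cell (moderated_t mode)
#' @param alpha FDR cutoff (default 0.05)
#' @param lfcMin minimum log2 fold change (default 0 for expression;
#'   use 0.25 for the accessibility rule)
#' @param minCells pseudobulk minimum (moderated_t mode)
#' @return list: \code{counts} (labels x labels matrix, entry [a, b] =
#'   features up in a vs b; diagonal 0), \code{skipped}, \code{rule}
#' @export
pairwiseRelatedness <- function(x, labels, mode = c("moderated_t", "wilcoxon"),
                                animals = NULL, alpha = 0.05, lfcMin = 0,
                                minCells = 15) {
  mode <- match.arg(mode)
  labs <- sort(unique(labels[!is.na(labels) & labels != UNCLASSIFIED]))
  stopifnot2(length(labs) >= 2, "need >= 2 labels")
  M <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  skipped <- character()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    a <- labs[i]; b <- labs[j]
    if (mode == "wilcoxon") {
      g1 <- which(!is.na(labels) & labels == a)
      g2 <- which(!is.na(labels) & labels == b)
      rs <- .rankSumRows(x, g1, g2)
      fdr <- p.adjust(rs$p, "BH")
      lfc <- log2(Matrix::rowMeans(x[, g1, drop = FALSE]) + 1) -
             log2(Matrix::rowMeans(x[, g2, drop = FALSE]) + 1)
      M[a, b] <- sum(fdr <= alpha & lfc >= lfcMin)
      M[b, a] <- sum(fdr <= alpha & -lfc >= lfcMin)
    } else {
      sel <- !is.na(labels) & labels %in% c(a, b)
      pb <- aggregatePseudobulk(x[, sel, drop = FALSE], labels[sel],
                                animals[sel], minCells = minCells)
      if (min(table(pb$meta$cellType)) < 2 ||
          length(unique(pb$meta$cellType)) < 2) {
        skipped <- c(skipped, paste(a, b, sep = " vs "))
        next
      }
      norm <- normalizeAndWeight(pb)
      fit <- fitModerated(norm, nSv = 0)
      ta <- fit$table[fit$table$contrast == a, ]
      fdr <- p.adjust(ta$pValue, "BH")
      M[a, b] <- sum(fdr <= alpha & ta$log2FC >= lfcMin & ta$t > 0)
      M[b, a] <- sum(fdr <= alpha & -ta$log2FC >= lfcMin & ta$t < 0)
    }
  }
  list(counts = M, skipped = skipped,
       rule = sprintf("FDR <= %g & log2FC >= %g (%s)", alpha, lfcMin, mode))
}

#' Cosine similarity between regions in PC space
#'
#' Down-samples nuclei per region, computes principal components of the
#' log-normalized expression, evaluates the cosine similarity between all
#' sampled nuclei pairs in PC space, and averages within region pairs.
#' Average-linkage hierarchical clustering of the region dissimilarities
#' provides a display order.
#'
#' @param counts genes x cells matrix
#' @param regions region label per cell
#' @param nPerRegion nuclei sampled per region (regions with fewer use all,
#'   flagged)
#' @param nPcs principal components retained
#' @param seed sampling seed
#' @return list: \code{similarity} (regions x regions mean cosine),
#'   \code{order} (dendrogram display order), \code{flagged}
#' @export
cosineRegionSimilarity <- function(counts, regions, nPerRegion = 500,
                                   nPcs = 20, seed = 1) {
  regions <- as.character(regions)
  regs <- sort(unique(regions))
  idx <- withSeed(seed, {
    unlist(lapply(regs, function(r) {
      i <- which(regions == r)
      if (length(i) > nPerRegion) sample(i, nPerRegion) else i
    }))
  })
  flagged <- regs[vapply(regs, function(r) sum(regions == r) < nPerRegion, TRUE)]
  cts <- as.matrix(counts[, idx, drop = FALSE])
  depth <- pmax(colSums(cts), 1)
  ln <- log1p(t(t(cts) / depth) * 1e4)
  nPcs <- min(nPcs, ncol(ln) - 1, nrow(ln))
  pcs <- prcomp(t(ln), rank. = nPcs, center = TRUE, scale. = FALSE)$x
  nrm <- sqrt(rowSums(pcs^2))
  keep <- nrm > 0
  V <- pcs[keep, , drop = FALSE] / nrm[keep]
  sims <- tcrossprod(V)
  grp <- regions[idx][keep]
  S <- matrix(NA_real_, length(regs), length(regs),
              dimnames = list(regs, regs))
  for (a in regs) for (b in regs) {
    block <- sims[grp == a, grp == b, drop = FALSE]
    if (a == b) {
      S[a, b] <- if (nrow(block) > 1)
        mean(block[upper.tri(block)]) else 1
    } else S[a, b] <- mean(block)
  }
  ord <- if (length(regs) > 2)
    hclust(stats::as.dist(1 - S), method = "average")$order
  else seq_along(regs)
  list(similarity = S, order = regs[ord], flagged = flagged)
}
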