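## Reference-based per-cell decomposition with doublet-mode classification
## and two-round (major class -> MSN subtype) labeling.
##
## The decomposition maximizes the Poisson (profile multinomial) likelihood
## of a cell's counts under a convex mixture of platform-adjusted reference
## profiles, by EM-type multiplicative updates on the simplex. EM guarantees
## the objective never decreases, which the test suite asserts.

UNCLASSIFIED <- "UNCLASSIFIED"

#' Estimate per-gene platform factors from pseudobulks
#'
#' Compares a spatial pseudobulk against a reference pseudobulk and returns
#' multiplicative per-gene factors \eqn{\gamma_g}: the ratio of
#' depth-normalized means after additive (pseudo-count) smoothing, clamped
#' to \eqn{[0.05, 20]}. Genes absent (zero) in either pseudobulk fall back
#' to \eqn{\gamma = 1}. Additive smoothing shrinks low-count ratios toward 1
#' while preserving genuine per-gene shifts.
#'
#' @param spatialPseudobulk,referencePseudobulk nonnegative per-gene totals
#'   (named, same genes)
#' @param smoothing pseudo-count added per gene before normalization
#' @return list with \code{gamma} (named numeric) and \code{smoothing}
#' @export
estimatePlatformFactors <- function(spatialPseudobulk, referencePseudobulk,
                                    smoothing = 0.5) {
  sp <- spatialPseudobulk; rf <- referencePseudobulk
  stopifnot2(all(sp >= 0) && all(rf >= 0), "pseudobulks must be nonnegative")
  stopifnot2(sum(sp) > 0 && sum(rf) > 0, "all-zero pseudobulk")
  G <- length(sp)
  pSp <- (sp + smoothing) / (sum(sp) + smoothing * G)
  pRf <- (rf + smoothing) / (sum(rf) + smoothing * G)
  gamma <- pSp / pRf
  gamma[sp == 0 | rf == 0] <- 1
  gamma <- pmin(pmax(gamma, 0.05), 20)
  names(gamma) <- names(sp)
  list(gamma = gamma, smoothing = smoothing)
}

## Platform-adjusted, per-type-normalized profiles (types x genes).
.adjustedProfiles <- function(panel, factors = NULL) {
  P <- panel@mu
  if (!is.null(factors)) {
    g <- if (is.list(factors)) factors$gamma else factors
    P <- sweep(P, 2, g[panel@geneIds], "*")
  }
  P / rowSums(P)
}

#' Decompose cells over reference profiles
#'
#' Estimates, for each cell, mixture weights over the reference types that
#' maximize the Poisson profile likelihood
#' \eqn{\sum_g y_g \log(\sum_t w_t p_{t,g})} on the simplex, where
#' \eqn{p_{t,g}} are platform-adjusted normalized profiles. Fitted by
#' multiplicative (EM) updates from a uniform start; deterministic given the
#' inputs. Cells with zero counts get NA weights (they are rejected).
#'
#' @param counts genes x cells count matrix (a single cell may be passed as
#'   a vector to [decomposeCell()])
#' @param panel a \linkS4class{ReferencePanel}
#' @param factors optional platform factors from [estimatePlatformFactors()]
#' @param tol convergence tolerance on the largest weight change
#' @param maxIter iteration cap
#' @param trace if TRUE, attach the total log-likelihood after every
#'   iteration as attribute \code{"llTrace"} (EM ascent diagnostics)
#' @return cells x types weight matrix (rows sum to 1; NA rows for
#'   zero-count cells)
#' @export
decomposeCells <- function(counts, panel, factors = NULL,
                           tol = 1e-8, maxIter = 1000, trace = FALSE) {
  P <- .adjustedProfiles(panel, factors)          # T x G
  Y <- Matrix::t(methods::as(counts, "CsparseMatrix"))  # C x G
  C <- nrow(Y); T <- nrow(P)
  depth <- Matrix::rowSums(Y)
  W <- matrix(1 / T, C, T, dimnames = list(rownames(Y), panel@typeIds))
  active <- depth > 0
  if (any(active)) {
    Ya <- as.matrix(Y[active, , drop = FALSE])  # dense: fast EM arithmetic
    Wa <- W[active, , drop = FALSE]
    da <- depth[active]
    tP <- t(P)
    llTrace <- if (trace) numeric() else NULL
    live <- seq_len(nrow(Wa))        # cells whose weights still move
    for (it in seq_len(maxIter)) {
      Wl <- Wa[live, , drop = FALSE]
      denom <- Wl %*% P                       # cells x genes mixture rates
      Wnew <- Wl * ((Ya[live, , drop = FALSE] / denom) %*% tP) / da[live]
      delta <- apply(abs(Wnew - Wl), 1, max)
      Wa[live, ] <- Wnew
      if (trace) llTrace <- c(llTrace, sum(.mixLogLik(Ya, Wa, P)))
      live <- live[delta >= tol]
      if (!length(live)) break
    }
    W[active, ] <- Wa
  }
  W[!active, ] <- NA_real_
  if (trace) attr(W, "llTrace") <- llTrace
  W
}

#' @rdname decomposeCells
#' @param cellCounts count vector over panel genes for one cell
#' @param minCounts minimum total counts (default 1: cells with at least one
#'   detected transcript)
#' @export
decomposeCell <- function(cellCounts, panel, factors = NULL, minCounts = 1,
                          tol = 1e-8, maxIter = 1000) {
  if (sum(cellCounts) < minCounts)
    return(setNames(rep(NA_real_, length(panel@typeIds)), panel@typeIds))
  W <- decomposeCells(matrix(cellCounts, ncol = 1), panel, factors,
                      tol = tol, maxIter = maxIter)
  setNames(W[1, ], panel@typeIds)
}

## Log-likelihood of cells (C x G counts) under fixed per-cell mixtures
## (C x T weights) of profiles P (T x G).
.mixLogLik <- function(Y, W, P) {
  lam <- pmax(W %*% P, 1e-300)
  as.vector(Matrix::rowSums(Y * log(lam)))
}

## Best two-type mixture log-likelihood per cell, searching pairs among each
## cell's top `nCandidates` singlet types; 1D EM vectorized across cells.
.bestPairFit <- function(Y, P, singletLL, nCandidates = 3,
                         tol = 1e-6, maxIter = 200) {
  Y <- as.matrix(Y)
  C <- nrow(Y); T <- nrow(P)
  nCandidates <- min(nCandidates, T)
  rk <- t(apply(singletLL, 1, function(z) order(z, decreasing = TRUE)))
  cand <- rk[, seq_len(nCandidates), drop = FALSE]
  bestLL <- rep(-Inf, C); bestPair <- matrix(NA_integer_, C, 2)
  bestW <- rep(NA_real_, C)
  depth <- pmax(rowSums(Y), 1)
  pairs <- utils::combn(seq_len(nCandidates), 2)
  for (j in seq_len(ncol(pairs))) {
    t1 <- cand[, pairs[1, j]]; t2 <- cand[, pairs[2, j]]
    P1 <- P[t1, , drop = FALSE]; P2 <- P[t2, , drop = FALSE]
    w <- rep(0.5, C)
    live <- seq_len(C)
    for (it in seq_len(maxIter)) {
      wl <- w[live]
      lam <- wl * P1[live, , drop = FALSE] +
        (1 - wl) * P2[live, , drop = FALSE]
      post <- (wl * P1[live, , drop = FALSE]) / pmax(lam, 1e-300)
      wNew <- rowSums(Y[live, , drop = FALSE] * post) / depth[live]
      moved <- abs(wNew - wl)
      w[live] <- wNew
      live <- live[moved >= tol]
      if (!length(live)) break
    }
    ll <- rowSums(Y * log(pmax(w * P1 + (1 - w) * P2, 1e-300)))
    upd <- ll > bestLL
    bestLL[upd] <- ll[upd]
    bestPair[upd, 1] <- t1[upd]; bestPair[upd, 2] <- t2[upd]
    bestW[upd] <- w[upd]
  }
  list(ll = bestLL, pair = bestPair, w = bestW)
}

#' Classify cells as singlet / doublet / rejected
#'
#' Compares, per cell, the best single-type log-likelihood against the best
#' two-type mixture. Improvement below \code{llMargin} nats gives a singlet;
#' improvement of at least \code{2 * llMargin} with both pair weights
#' \eqn{\ge 0.25} gives a certain doublet; anything between is an uncertain
#' doublet. Independently, a cell is rejected when its mean per-count
#' log-likelihood under the best fitted model falls more than \code{rejectSd}
#' standard deviations below that model's expectation (exact multinomial
#' moments at the cell's depth — the matched-depth calibration of the
#' rejection floor).
#'
#' @inheritParams decomposeCells
#' @param llMargin singlet-vs-doublet margin in nats (default 10)
#' @param rejectSd rejection floor in model standard deviations (default 6)
#' @param nCandidates pair search is restricted to each cell's top singlet
#'   types (default 3)
#' @return data.frame with columns \code{mode}, \code{bestType},
#'   \code{secondType}, \code{pairWeight}, \code{singletLL}, \code{pairLL}
#' @export
classifyMode <- function(counts, panel, factors = NULL, llMargin = 10,
                         rejectSd = 6, nCandidates = 3) {
  P <- .adjustedProfiles(panel, factors)
  Y <- Matrix::t(methods::as(counts, "CsparseMatrix"))
  C <- nrow(Y)
  depth <- Matrix::rowSums(Y)
  logP <- log(pmax(P, 1e-300))
  singletLL <- as.matrix(Y %*% t(logP))            # C x T
  bestType <- max.col(singletLL, ties.method = "first")
  bestLL <- singletLL[cbind(seq_len(C), bestType)]
  pairFit <- .bestPairFit(Y, P, singletLL, nCandidates = nCandidates)
  improvement <- pairFit$ll - bestLL
  minW <- pmin(pairFit$w, 1 - pairFit$w)
  mode <- ifelse(improvement < llMargin, "singlet",
          ifelse(improvement >= 2 * llMargin & minW >= 0.25,
                 "doublet_certain", "doublet_uncertain"))
  ## rejection floor: the best fitted model's mean per-count log-likelihood
  ## against its own expectation (exact multinomial moments at the cell's
  ## depth) — cells fitting no singlet or pair are rejected
  t1 <- pairFit$pair[, 1]; t2 <- pairFit$pair[, 2]
  pmix <- pairFit$w * P[t1, , drop = FALSE] +
    (1 - pairFit$w) * P[t2, , drop = FALSE]
  lmix <- log(pmax(pmix, 1e-300))
  ex <- rowSums(pmix * lmix)                # E[log p] under the fitted model
  vx <- rowSums(pmix * lmix^2) - ex^2
  fitLL <- pmax(bestLL, pairFit$ll)
  floorLL <- ex - rejectSd * sqrt(vx / pmax(depth, 1))
  obs <- fitLL / pmax(depth, 1)
  mode[depth == 0 | obs < floorLL] <- "rejected"
  data.frame(
    mode = mode, bestType = panel@typeIds[bestType],
    secondType = panel@typeIds[ifelse(is.na(pairFit$pair[, 2]), NA,
                                      pairFit$pair[, 2])],
    pairWeight = pairFit$w, singletLL = bestLL, pairLL = pairFit$ll,
    row.names = rownames(Y), stringsAsFactors = FALSE)
}

#' Assign labels by the strict 0.5-weight rule
#'
#' A cell receives the label whose decomposition weight strictly exceeds
#' \code{threshold} (default 0.5); otherwise it is \code{UNCLASSIFIED}.
#' Rejected cells receive no label and are excluded from labeled output
#' downstream. Ties at the threshold do not assign (strict inequality).
#'
#' @param weights cells x types weight matrix from [decomposeCells()]
#' @param mode character vector of modes from [classifyMode()] (optional;
#'   all-singlet assumed if missing)
#' @param threshold assignment threshold (default 0.5)
#' @return data.frame with \code{assigned_label} (NA for rejected),
#'   \code{maxWeight}, \code{mode}
#' @export
assignLabel <- function(weights, mode = NULL, threshold = 0.5) {
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1,
                                               dimnames = list(NULL, names(weights)))
  if (is.null(mode)) mode <- rep("singlet", nrow(weights))
  maxIdx <- apply(weights, 1, function(w) if (all(is.na(w))) NA_integer_
                  else which.max(w))
  maxW <- ifelse(is.na(maxIdx), NA_real_,
                 weights[cbind(seq_len(nrow(weights)), maxIdx)])
  lab <- ifelse(!is.na(maxW) & maxW > threshold,
                colnames(weights)[ifelse(is.na(maxIdx), 1, maxIdx)],
                UNCLASSIFIED)
  lab[mode == "rejected" | is.na(maxW)] <- NA_character_
  data.frame(assigned_label = lab, maxWeight = maxW, mode = mode,
             row.names = rownames(weights), stringsAsFactors = FALSE)
}

#' Two-round hierarchical labeling
#'
#' Round 1 decomposes every cell against the major-class panel and assigns
#' labels by the 0.5 rule; cells labeled as the MSN class are then
#' re-decomposed against the subtype panel and re-assigned (round 2).
#' Rejected cells are excluded from the labeled output; non-MSN cells keep
#' their round-1 label. The summary reports the labeled-cell count and the
#' MSN fraction of all cells and of neurons.
#'
#' @param cells a SpatialCellTable
#' @param classPanel major-class \linkS4class{ReferencePanel}
#' @param subtypePanel MSN-subtype \linkS4class{ReferencePanel}
#' @param msnClass label in \code{classPanel} naming the MSN class
#' @param neuronClasses labels counted as neurons for the summary
#' @param factors,subtypeFactors optional platform factors per round
#' @param threshold assignment threshold
#' @param ... passed to [classifyMode()]
#' @return list with \code{cells} (SpatialCellTable with
#'   \code{assigned_label}, \code{label_round}, \code{label_mode} columns)
#'   and \code{summary}
#' @export
hierarchicalLabel <- function(cells, classPanel, subtypePanel,
                              msnClass = "MSN",
                              neuronClasses = c("MSN", "Interneuron"),
                              factors = NULL, subtypeFactors = NULL,
                              threshold = 0.5, ...) {
  cts <- SummarizedExperiment::assay(cells, "counts")
  W1 <- decomposeCells(cts[classPanel@geneIds, , drop = FALSE], classPanel,
                       factors)
  m1 <- classifyMode(cts[classPanel@geneIds, , drop = FALSE], classPanel,
                     factors, ...)
  a1 <- assignLabel(W1, m1$mode, threshold)
  lab <- a1$assigned_label
  rnd <- rep("major_class", ncol(cells))
  isMsn <- !is.na(lab) & lab == msnClass
  if (!any(isMsn)) {
    warning("no cell labeled as the MSN class; subtype round skipped")
  } else {
    sub <- cts[subtypePanel@geneIds, isMsn, drop = FALSE]
    W2 <- decomposeCells(sub, subtypePanel, subtypeFactors)
    m2 <- classifyMode(sub, subtypePanel, subtypeFactors, ...)
    a2 <- assignLabel(W2, m2$mode, threshold)
    lab[isMsn] <- a2$assigned_label
    rnd[isMsn] <- "msn_subtype"
  }
  cells$assigned_label <- lab
  cells$label_round <- rnd
  cells$label_mode <- m1$mode
  labeled <- !is.na(lab) & lab != UNCLASSIFIED
  isNeuron <- !is.na(a1$assigned_label) & a1$assigned_label %in% neuronClasses
  summary <- list(
    nCells = ncol(cells),
    nLabeled = sum(labeled),
    nMsn = sum(isMsn),
    msnFractionOfCells = sum(isMsn) / ncol(cells),
    msnFractionOfNeurons = if (any(isNeuron)) sum(isMsn) / sum(isNeuron)
                           else NA_real_,
    nRejected = sum(m1$mode == "rejected"))
  list(cells = cells, summary = summary)
}
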