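## Neighborhood-composition spatial niches and data-driven tissue
## demarcation: each cell is described by the cell-type composition of its
## k nearest labeled neighbors, compositions are k-means clustered, and the
## niche with the highest MSN proportion demarcates the striatum.

## Exact k-nearest labeled neighbors by chunked brute force with a
## deterministic (distance, index) tie-break. Returns an n x k index matrix
## into the labeled-cell set.
.knnLabeled <- function(x, y, labeledIdx, k, chunk = 512L) {
  n <- length(x)
  nl <- length(labeledIdx)
  lx <- x[labeledIdx]; ly <- y[labeledIdx]
  out <- matrix(NA_integer_, n, k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(x[idx], lx, "-")^2 + outer(y[idx], ly, "-")^2
    for (r in seq_along(idx)) {
      i <- idx[r]
      di <- d2[r, ]
      self <- which(labeledIdx == i)
      if (length(self)) di[self] <- Inf
      ord <- order(di, seq_len(nl))          # ties: smaller index first
      out[i, ] <- ord[seq_len(k)]
    }
  }
  out
}

#' Neighbor-label composition per cell
#'
#' For every cell, counts the labels among its \code{k} nearest labeled
#' cells (Euclidean distance, self excluded, deterministic tie-break by
#' distance then cell order). Unlabeled cells contribute to no one's
#' composition but still receive a composition row from their labeled
#' neighbors. Every row sums to exactly \code{k}.
#'
#' @param x,y cell coordinates (microns)
#' @param labels character label per cell (NA / UNCLASSIFIED = unlabeled)
#' @param k neighbors per cell (default 30, the scale of the niche assay)
#' @return integer matrix, cells x observed labels
#' @export
neighborhoodComposition <- function(x, y, labels, k = 30) {
  n <- length(x)
  labeled <- which(!is.na(labels) & labels != UNCLASSIFIED)
  stopifnot2(length(labeled) >= k + 1,
             "need at least k+1 labeled cells in the section")
  labs <- sort(unique(labels[labeled]))
  nn <- .knnLabeled(x, y, labeled, k)
  neighLab <- matrix(match(labels[labeled][nn], labs), nrow(nn), k)
  comp <- matrix(0L, n, length(labs), dimnames = list(NULL, labs))
  for (j in seq_len(k))
    comp[cbind(seq_len(n), neighLab[, j])] <-
      comp[cbind(seq_len(n), neighLab[, j])] + 1L
  comp
}

#' Cluster compositions into spatial niches
#'
#' K-means (Lloyd, fixed seed, \code{nstart} restarts) on the
#' neighbor-composition matrix. The striatal niche is the cluster whose
#' member rows have the highest proportion of MSN labels; the striatum mask
#' is the set of cells in that niche. Used both to validate anatomical
#' boundaries and to refine the striatal crop — the same operation.
#'
#' @param composition cells x labels matrix from [neighborhoodComposition()]
#' @param nClusters requested niches (default 30)
#' @param seed RNG seed for the k-means restarts
#' @param msnLabels labels counted as MSN when ranking niches (default: any
#'   label containing "MSN", case-insensitive)
#' @param nstart k-means restarts
#' @return a \linkS4class{NicheModel}
#' @export
clusterNiches <- function(composition, nClusters = 30, seed = 1,
                          msnLabels = NULL, nstart = 10) {
  if (is.null(msnLabels))
    msnLabels <- grep("msn", colnames(composition), ignore.case = TRUE,
                      value = TRUE)
  uniq <- unique(composition)
  if (nrow(uniq) == 1) {
    warning("all composition rows identical; single effective niche")
    km <- list(cluster = rep(1L, nrow(composition)), centers = uniq)
    nClusters <- 1L
  } else {
    if (nClusters > nrow(uniq)) {
      warning("fewer distinct composition rows than clusters; reducing k")
      nClusters <- nrow(uniq)
    }
    km <- withSeed(seed, suppressWarnings(
      kmeans(composition, centers = nClusters, nstart = nstart,
             iter.max = 100, algorithm = "Lloyd")))
  }
  k <- sum(composition[1, ])
  msnCols <- intersect(msnLabels, colnames(composition))
  msnFrac <- vapply(seq_len(nClusters), function(cl) {
    rows <- km$cluster == cl
    if (!any(rows)) return(-Inf)
    sum(composition[rows, msnCols, drop = FALSE]) / (sum(rows) * k)
  }, 0)
  new("NicheModel",
      kNeighbors = as.integer(k), nClusters = as.integer(nClusters),
      composition = composition, nicheOfCell = as.integer(km$cluster),
      striatalNiche = as.integer(which.max(msnFrac)),
      centroids = as.matrix(km$centers), msnLabels = as.character(msnCols))
}

#' Run the spatial niche assay on a labeled section
#'
#' Convenience wrapper: composition of the k nearest labeled neighbors,
#' then k-means niches, returning the model and the per-cell striatum flag.
#'
#' @param cells a labeled SpatialCellTable (column \code{assigned_label}, or
#'   \code{labelCol})
#' @param k neighbors per cell
#' @param nClusters niches
#' @param labelCol colData column holding labels
#' @param ... passed to [clusterNiches()]
#' @return list with \code{model} (\linkS4class{NicheModel}) and
#'   \code{inStriatum} (logical per cell)
#' @export
nicheAssay <- function(cells, k = 30, nClusters = 30,
                       labelCol = "assigned_label", ...) {
  labels <- SummarizedExperiment::colData(cells)[[labelCol]]
  comp <- neighborhoodComposition(cells$x_um, cells$y_um, labels, k = k)
  model <- clusterNiches(comp, nClusters = nClusters, ...)
  list(model = model, inStriatum = striatumMask(model))
}
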