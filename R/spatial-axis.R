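## Spatial axes and the regression-discontinuity test: raw-coordinate or
## nonlinear 1D (isomap) axes, Otsu boundary detection on the axis
## histogram, and a Gaussian GLM testing for a discrete jump at the
## boundary while controlling for the continuous spatial trend.

#' One-dimensional spatial embedding
#'
#' \code{mode = "axis_x"} / \code{"axis_y"} return the raw coordinate.
#' \code{mode = "isomap_1d"} builds a symmetric k-nearest-neighbor graph on
#' (x, y), computes graph shortest-path (geodesic) distances, and returns
#' the first classical-MDS coordinate — a nonlinear 1D embedding of the
#' anatomical gradient. The sign is fixed so the coordinate correlates
#' positively with x (with y on ties). Sections larger than
#' \code{landmark} cells are embedded through a seeded landmark subsample;
#' remaining cells take the coordinate of their nearest landmark.
#'
#' @param x,y coordinates (microns)
#' @param mode one of \code{"axis_x"}, \code{"axis_y"}, \code{"isomap_1d"}
#' @param nNeighbors kNN graph degree for isomap mode
#' @param landmark maximum cells used for the geodesic computation
#' @param seed seed for the landmark subsample
#' @return numeric coordinate per cell
#' @export
embed1d <- function(x, y, mode = c("axis_x", "axis_y", "isomap_1d"),
                    nNeighbors = 15, landmark = 2000, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "axis_x") return(x)
  if (mode == "axis_y") return(y)
  n <- length(x)
  stopifnot2(n >= nNeighbors + 1, "need at least nNeighbors + 1 cells")
  sub <- if (n > landmark) withSeed(seed, sort(sample.int(n, landmark)))
         else seq_len(n)
  xs <- x[sub]; ys <- y[sub]; m <- length(sub)
  geo <- .isomapGeodesics(xs, ys, nNeighbors)
  coordSub <- cmdscale(geo, k = 1)[, 1]
  sgn <- sign(cor(coordSub, xs))
  if (!is.finite(sgn) || sgn == 0) sgn <- sign(cor(coordSub, ys))
  if (!is.finite(sgn) || sgn == 0) sgn <- 1
  coordSub <- sgn * coordSub
  if (m == n) return(coordSub)
  ## non-landmark cells: coordinate of the nearest landmark
  out <- numeric(n)
  out[sub] <- coordSub
  rest <- setdiff(seq_len(n), sub)
  for (i in rest) {
    j <- which.min((xs - x[i])^2 + (ys - y[i])^2)
    out[i] <- coordSub[j]
  }
  out
}

## Geodesic (graph shortest-path) distances over the symmetric kNN graph.
.isomapGeodesics <- function(xs, ys, nNeighbors) {
  m <- length(xs)
  d <- as.matrix(dist(cbind(xs, ys)))
  adj <- matrix(0, m, m)
  for (i in seq_len(m)) {
    nb <- order(d[i, ])[2:(nNeighbors + 1)]
    adj[i, nb] <- d[i, nb]
  }
  adj <- pmax(adj, t(adj))                    # symmetric union graph
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  geo <- igraph::distances(g)
  if (any(!is.finite(geo)))
    stop("kNN graph is disconnected; raise nNeighbors")
  geo
}

#' Otsu threshold on a 1D coordinate
#'
#' Histograms the coordinate into \code{nBins} equal-width bins and returns
#' the interior bin edge maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} — an exhaustive scan over all
#' edges. Ties are broken toward the edge closest to the median coordinate.
#'
#' @param coords numeric vector with at least 2 distinct values
#' @param nBins histogram bins (default 128)
#' @return the threshold (a bin edge)
#' @export
otsuBoundary <- function(coords, nBins = 128) {
  rng <- range(coords)
  stopifnot2(diff(rng) > 0, "constant coordinate: no boundary")
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1)
  bin <- findInterval(coords, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cnt <- tabulate(bin, nBins)
  mids <- (breaks[-1] + breaks[-(nBins + 1)]) / 2
  n <- sum(cnt)
  cw <- cumsum(cnt)
  cm <- cumsum(cnt * mids)
  tot <- cm[nBins]
  j <- seq_len(nBins - 1)                       # edge after bin j
  w0 <- cw[j] / n; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- cm[j] / pmax(cw[j], 1)
  mu1 <- (tot - cm[j]) / pmax(n - cw[j], 1)
  bc <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- max(bc)
  tie <- which(bc >= best - 1e-12 * max(best, 1e-300))
  edges <- breaks[tie + 1]
  edges[which.min(abs(edges - median(coords)))]
}

#' Spatial regression-discontinuity test
#'
#' Centers the axis at the boundary and fits the Gaussian working model
#' \deqn{expr = \beta_0 + \beta_1 1[coord > boundary] +
#'   \beta_2 (coord - boundary) + \epsilon}
#' by least squares. The null is that expression is a linear function of
#' position; a two-sided Wald test on \eqn{\beta_1} (normal reference, as in
#' a Gaussian GLM) asks whether the boundary explains an abrupt jump beyond
#' the continuous trend. No interaction (side-specific slope) term is
#' included by default, matching the single-slope working model;
#' \code{separateSlopes = TRUE} adds it.
#'
#' @param expr per-cell expression of one gene (normalized scale)
#' @param coords per-cell axis coordinate
#' @param boundary boundary on the axis (e.g. from [otsuBoundary()])
#' @param minSide minimum cells required on each side (default 20)
#' @param separateSlopes add a slope x side interaction (off by default)
#' @param gene,sectionId optional identifiers carried into the result
#' @return one-row data.frame: \code{gene}, \code{boundary},
#'   \code{intercept}, \code{jumpBeta}, \code{slopeBeta}, \code{jumpSe},
#'   \code{pValue}, \code{nLeft}, \code{nRight}, \code{sectionId}
#' @export
rddTest <- function(expr, coords, boundary, minSide = 20,
                    separateSlopes = FALSE, gene = NA_character_,
                    sectionId = NA_character_) {
  ctr <- coords - boundary
  pos <- as.numeric(ctr > 0)
  nLeft <- sum(pos == 0); nRight <- sum(pos == 1)
  stopifnot2(nLeft >= minSide && nRight >= minSide,
             "need at least minSide cells on each side of the boundary")
  X <- cbind(1, pos, ctr)
  if (separateSlopes) X <- cbind(X, pos * ctr)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-14) stop("rank-deficient design")
  beta <- solve(XtX, crossprod(X, expr))
  fit <- X %*% beta
  rss <- sum((expr - fit)^2)
  df <- length(expr) - ncol(X)
  sigma2 <- rss / df
  covBeta <- sigma2 * solve(XtX)
  se <- sqrt(diag(covBeta))
  if (sigma2 < 1e-300) {            # degenerate noiseless fit (convention)
    p <- if (abs(beta[2]) < 1e-12) 1 else 0
    se[2] <- 0
  } else {
    p <- 2 * pnorm(-abs(beta[2] / se[2]))
  }
  data.frame(gene = gene, boundary = boundary,
             intercept = beta[1], jumpBeta = beta[2], slopeBeta = beta[3],
             jumpSe = se[2], pValue = p, nLeft = nLeft, nRight = nRight,
             sectionId = sectionId, stringsAsFactors = FALSE)
}

#' Per-section RDD pipeline for a gene and a type pair
#'
#' The full discontinuity workflow on one section: pool the cells of the
#' two compared types, embed them on the requested axis, find the boundary
#' by Otsu thresholding of the pooled axis coordinates (the bimodal spatial
#' occupancy of the two types drives the boundary), and test the gene's
#' log1p depth-normalized expression for a jump. Sections are always tested
#' separately — per-section p-values are reported, never pooled across
#' animals.
#'
#' @param cells a labeled SpatialCellTable (one section)
#' @param gene gene to test
#' @param types character vector of the two cell-type labels being compared
#' @param mode axis mode, see [embed1d()]
#' @param labelCol colData column holding labels
#' @param scale depth-normalization scale factor (counts per \code{scale})
#' @param ... passed to [rddTest()]
#' @return one-row data.frame as [rddTest()]
#' @export
rddPipeline <- function(cells, gene, types, mode = "axis_x",
                        labelCol = "assigned_label", scale = 100, ...) {
  labels <- SummarizedExperiment::colData(cells)[[labelCol]]
  keep <- !is.na(labels) & labels %in% types
  stopifnot2(any(keep), "no cells of the requested types")
  sub <- cells[, keep]
  coords <- embed1d(sub$x_um, sub$y_um, mode)
  boundary <- otsuBoundary(coords)
  cts <- SummarizedExperiment::assay(sub, "counts")
  depth <- pmax(Matrix::colSums(cts), 1)
  expr <- log1p(as.numeric(cts[gene, ]) / depth * scale)
  sec <- unique(sub$section_id)
  rddTest(expr, coords, boundary, gene = gene,
          sectionId = if (length(sec) == 1) sec else NA_character_, ...)
}
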