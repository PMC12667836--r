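test_that("axis modes return raw coordinates; isomap preserves 1D order", {
  set.seed(1)
  x <- runif(60, 0, 100); y <- runif(60, 0, 100)
  expect_identical(embed1d(x, y, "axis_x"), x)
  expect_identical(embed1d(x, y, "axis_y"), y)
  ## points on a line: the isomap coordinate is an affine map of arc length
  xl <- seq(0, 100, length.out = 50); yl <- rep(0, 50)
  emb <- embed1d(xl, yl, "isomap_1d", nNeighbors = 5)
  expect_equal(cor(emb, xl, method = "spearman"), 1)
})

test_that("a disconnected kNN graph asks for a larger neighborhood", {
  set.seed(2)
  th <- sort(runif(60, 0, pi / 2))   # random spacing splits the graph
  expect_error(embed1d(cos(th) * 100, sin(th) * 100, "isomap_1d",
                       nNeighbors = 6), "nNeighbors")
})

test_that("isomap geodesics match a brute-force shortest-path oracle", {
  set.seed(2)
  th <- seq(0, pi / 2, length.out = 60) + rnorm(60, 0, 0.002)
  th <- sort(th)
  x <- cos(th) * 100; y <- sin(th) * 100
  k <- 6
  geo <- striatlas:::.isomapGeodesics(x, y, k)
  ## oracle: rebuild the symmetric kNN graph and run Floyd-Warshall
  m <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  adj <- matrix(Inf, m, m); diag(adj) <- 0
  for (i in 1:m) {
    nb <- order(d[i, ])[2:(k + 1)]
    adj[i, nb] <- d[i, nb]; adj[nb, i] <- d[i, nb]
  }
  for (mid in 1:m) for (i in 1:m) {
    thru <- adj[i, mid] + adj[mid, ]
    adj[i, ] <- pmin(adj[i, ], thru)
  }
  expect_equal(geo, adj, tolerance = 1e-10, ignore_attr = TRUE)
  ## ordering along the arc is preserved
  emb <- embed1d(x, y, "isomap_1d", nNeighbors = k)
  expect_equal(abs(cor(emb, th, method = "spearman")), 1)
})

test_that("Otsu thresholding returns the between-class-variance maximizer", {
  expect_equal(otsuBoundary(c(0, 0, 0, 10, 10, 10)), 5.0)
  expect_equal(otsuBoundary(rep(c(0, 1), 20)), 0.5)
  set.seed(3)
  mix <- c(rnorm(100, 0), rnorm(100, 6))
  t0 <- otsuBoundary(mix)
  expect_gt(t0, 2); expect_lt(t0, 4)
  expect_equal(t0, otsuOracle(mix))
  expect_error(otsuBoundary(rep(3, 10)), "constant")
})

test_that("Otsu equals the exhaustive scan oracle on random mixtures", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(50:300, 1)
    mu2 <- runif(1, 2, 8)
    v <- c(rnorm(n, 0, runif(1, 0.5, 1.5)), rnorm(n, mu2, runif(1, 0.5, 1.5)))
    expect_identical(otsuBoundary(v), otsuOracle(v))
  }
})

test_that("noiseless geometries give exact RDD coefficients", {
  coords <- c(seq(-10, -0.5, 0.25), seq(0.5, 10, 0.25))
  step <- ifelse(coords > 0, 5, 0)
  r <- rddTest(step, coords, 0)
  expect_equal(r$jumpBeta, 5, tolerance = 1e-10)
  expect_equal(r$slopeBeta, 0, tolerance = 1e-10)
  expect_equal(r$pValue, 0)        # noiseless nonzero jump convention
  grad <- 2 * coords
  r2 <- rddTest(grad, coords, 0)
  expect_equal(r2$jumpBeta, 0, tolerance = 1e-10)
  expect_equal(r2$pValue, 1)       # noiseless zero-jump convention
})

test_that("RDD coefficients and SEs match the least-squares oracle", {
  set.seed(5)
  coords <- runif(200, -3, 3)
  expr <- 1 + 0.5 * (coords > 0) + 0.3 * coords + rnorm(200)
  r <- rddTest(expr, coords, 0)
  ## oracle: QR-based lm fit of the same working model
  pos <- as.numeric(coords > 0)
  fit <- lm(expr ~ pos + coords)
  sm <- summary(fit)$coefficients
  expect_equal(r$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(r$jumpBeta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(r$slopeBeta, unname(coef(fit)[3]), tolerance = 1e-10)
  expect_equal(r$jumpSe, unname(sm[2, 2]), tolerance = 1e-10)
  expect_equal(r$nLeft + r$nRight, 200)
})

test_that("RDD inference is invariant to affine rescaling of the axis", {
  set.seed(6)
  coords <- runif(150, 0, 10)
  expr <- 2 + (coords > 5) + 0.2 * coords + rnorm(150, 0, 0.5)
  r1 <- rddTest(expr, coords, 5)
  a <- 7.3; b <- -12
  r2 <- rddTest(expr, a * coords + b, a * 5 + b)
  expect_equal(r1$jumpBeta, r2$jumpBeta, tolerance = 1e-10)
  expect_equal(r1$pValue, r2$pValue, tolerance = 1e-10)
  expect_equal(r1$slopeBeta, r2$slopeBeta * a, tolerance = 1e-10)
})

test_that("RDD guards its preconditions", {
  coords <- seq(-1, 1, length.out = 100)
  expect_error(rddTest(rnorm(100), coords, 2), "minSide")
  expect_error(rddTest(rnorm(100), coords, 0.97), "minSide")
})

test_that("reference correlation is exact for matching means and hand toys", {
  cfg <- smallConfig(seed = 1, nTypes = 2, nGenes = 10, markersPerType = 2)
  panel <- makeReference(cfg)
  ## cells whose counts are exactly proportional to the reference profile
  cts <- sapply(1:25, function(i) round(profileMatrix(panel)[1, ] * 2800))
  rownames(cts) <- geneIds(panel)
  sce <- SpatialCellTable(cts, data.frame(cell_id = paste0("c", 1:25),
                                          assigned_label = "T1"))
  rc <- referenceCorrelation(sce, panel, minCells = 10)
  expect_equal(rc$r2[rc$type == "T1"], 1, tolerance = 1e-6)
  expect_equal(rc$flag[rc$type == "T2"], "too_few_cells")
  ## hand-computed Pearson r on the transformed vectors
  m <- log1p(rowMeans(cts / sum(cts[, 1])) * 100)
  ref <- log1p(profileMatrix(panel)[1, ] * 100)
  rHand <- sum((m - mean(m)) * (ref - mean(ref))) /
    sqrt(sum((m - mean(m))^2) * sum((ref - mean(ref))^2))
  expect_equal(rc$r[rc$type == "T1"], unname(rHand), tolerance = 1e-12)
})

test_that("unrelated expression gives near-zero reference correlation", {
  set.seed(7)
  cfg <- simulationConfig(seed = 2, nTypes = 3, nGenes = 366)
  panel <- makeReference(cfg)
  pvals <- replicate(20, {
    cts <- matrix(rpois(366 * 30, 2), 366,
                  dimnames = list(geneIds(panel), NULL))
    sce <- SpatialCellTable(cts, data.frame(cell_id = paste0("c", 1:30),
                                            assigned_label = "T1"))
    rc <- referenceCorrelation(sce, panel, minCells = 10)
    c(rc$r2[1], rc$pValue[1])
  })
  expect_lt(mean(pvals[1, ]), 0.1)
  expect_lt(mean(pvals[2, ] < 0.05), 0.25)
})

test_that("abundance percentages, fold changes and SEM follow their definitions", {
  mkSec <- function(id, rc, nA, nB) {
    data.frame(cell_id = paste0(id, seq_len(nA + nB)), x_um = 0, y_um = 0,
               section_id = id, rc_level_mm = rc, animal_id = "A1",
               species_id = "S1", true_type = NA,
               assigned_label = rep(c("A", "B"), c(nA, nB)))
  }
  cts <- function(n) matrix(1, 1, n, dimnames = list("G1", NULL))
  secs <- list(
    SpatialCellTable(cts(100), mkSec("s1", 0, 50, 50)),
    SpatialCellTable(cts(60), mkSec("s2", -2, 10, 50)))
  ag <- abundanceGradient(secs, group = c("A", "B"), pair = c("A", "B"))
  ps <- ag$perSection
  expect_equal(ps$percent[ps$section_id == "s1"], c(50, 50))
  fc <- ag$foldChange
  expect_equal(fc$foldChange[fc$section_id == "s1"], 1)
  expect_equal(fc$foldChange[fc$section_id == "s2"], 5)
  ## SEM across three sections at one level with percents 10/20/30
  secs3 <- list(
    SpatialCellTable(cts(100), mkSec("t1", 0, 10, 90)),
    SpatialCellTable(cts(100), mkSec("t2", 0, 20, 80)),
    SpatialCellTable(cts(100), mkSec("t3", 0, 30, 70)))
  ag3 <- abundanceGradient(secs3, group = c("A", "B"))
  semA <- ag3$sem$sem[ag3$sem$type == "A"]
  expect_equal(semA, 5.7735, tolerance = 1e-4)
  ## percentages within a section sum to 100
  expect_true(all(abs(tapply(ps$percent, ps$section_id, sum) - 100) < 1e-9))
})

test_that("LOESS smoothing is exactly linear on linear data", {
  set.seed(8)
  x <- sort(runif(30, 0, 10)); y <- 2 + 3 * x
  for (span in c(0.3, 0.75, 1)) {
    expect_equal(loessSmooth(x, y, span), y, tolerance = 1e-8)
  }
  expect_equal(loessSmooth(x, rep(4, 30), 0.5), rep(4, 30), tolerance = 1e-10)
})

test_that("LOESS fits equal a per-point weighted least-squares oracle", {
  set.seed(9)
  x <- sort(runif(10, 0, 1)); y <- sin(4 * x) + rnorm(10, 0, 0.1)
  span <- 0.6
  x0 <- x[4]
  fitAt <- loessSmooth(x, y, span, xout = x0)
  ## oracle: hand-built tricube weights over the span-fraction neighborhood
  q <- ceiling(span * 10)
  d <- abs(x - x0)
  nb <- order(d)[1:q]
  w <- (1 - (d[nb] / max(d[nb]))^3)^3
  or <- lm(y[nb] ~ I(x[nb] - x0), weights = w)
  expect_equal(fitAt, unname(coef(or)[1]), tolerance = 1e-8)
})

test_that("the mixed model reduces to OLS for one group and matches lme4", {
  set.seed(10)
  x <- 1:20; y <- 0.7 * x + rnorm(20)
  f <- lmmFit(y, x, rep("g", 20))
  expect_equal(f$beta, unname(coef(lm(y ~ x))[2]), tolerance = 1e-8)
  expect_equal(f$nGroups, 1)
  ## zero generative group variance: estimated random sd near 0, slope ~ OLS
  y2 <- 0.5 * rep(1:10, 2) + rnorm(20)
  f2 <- lmmFit(y2, rep(1:10, 2), rep(c("a", "b"), each = 10))
  expect_lt(f2$randomInterceptSd, 0.8)
  expect_equal(f2$beta, unname(coef(lm(y2 ~ rep(1:10, 2)))[2]),
               tolerance = 0.05)
  ## independent oracle: lme4 REML on a 5-group dataset
  skip_if_not_installed("lme4")
  set.seed(11)
  g <- rep(1:5, each = 12); xx <- rep(1:12, 5)
  yy <- 1.2 * xx + rep(rnorm(5, 0, 2), each = 12) + rnorm(60)
  mine <- lmmFit(yy, xx, g)
  lf <- lme4::lmer(yy ~ xx + (1 | g), REML = TRUE)
  expect_equal(mine$beta, unname(lme4::fixef(lf)[2]), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(mine$randomInterceptSd, vc$sdcor[1], tolerance = 0.01)
  expect_equal(mine$residualSd, vc$sdcor[2], tolerance = 0.01)
})

test_that("the RDD pipeline reports sections separately", {
  cfg <- smallConfig(seed = 13, territorySpec = list(
    rectTerritory(c("T1", "T2"), 0.002)))
  panel <- makeReference(cfg)
  res <- lapply(c("secA", "secB"), function(id) {
    s <- makeSection(panel, cfg, rcLevelMm = 0, sectionId = id)
    s <- injectDiscontinuity(s, "G001", "x", 500, jump = 4, noiseSd = 0.5)
    s$assigned_label <- s$true_type
    rddPipeline(s, "G001", c("T1", "T2"))
  })
  expect_equal(vapply(res, function(r) r$sectionId, ""), c("secA", "secB"))
  expect_true(all(vapply(res, function(r) r$pValue, 0) < 0.01))
})
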