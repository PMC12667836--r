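test_that("pseudobulk aggregation sums counts and applies the cell floor", {
  cts <- cbind(c(1, 2, 0), c(0, 3, 5))
  colnames(cts) <- c("c1", "c2"); rownames(cts) <- paste0("g", 1:3)
  pb <- aggregatePseudobulk(cts, c("A", "A"), c("x", "x"), minCells = 2)
  expect_equal(unname(pb$counts[, 1]), c(1, 5, 5))
  expect_equal(pb$meta$detectionRate, 1)
  ## detection rate counts genes with nonzero summed counts
  pb2 <- aggregatePseudobulk(cbind(c(0, 1, 2)), "A", "x", minCells = 1)
  expect_equal(pb2$meta$detectionRate, 2 / 3)
  ## an aggregate with 14 cells is excluded at the default floor of 15
  cts3 <- matrix(rpois(3 * 34, 2), 3, 34)
  rownames(cts3) <- paste0("g", 1:3)
  lab <- rep(c("A", "B"), c(14, 20)); an <- rep("x", 34)
  pb3 <- aggregatePseudobulk(cts3, lab, an)
  expect_equal(pb3$meta$cellType, "B")
  expect_equal(pb3$excluded$cellType, "A")
  ## conservation: surviving totals equal their member cells' totals
  expect_equal(sum(pb3$counts), sum(cts3[, lab == "B"]))
})

test_that("TMM factors and quality weights behave on identical and scaled samples", {
  set.seed(1)
  base <- rpois(300, 20)
  cts <- cbind(s1 = base, s2 = base, s3 = base, s4 = base)
  rownames(cts) <- paste0("g", 1:300)
  pb <- list(counts = cts,
             meta = data.frame(cellType = c("A", "A", "B", "B"),
                               animal = paste0("a", 1:4),
                               nCells = 20, detectionRate = 1))
  norm <- normalizeAndWeight(pb)
  expect_true(all(abs(norm$normFactors - 1) < 1e-8))
  expect_true(all(abs(norm$scaleFactors - 1) < 1e-8))
  ## quality weights are positive, finite, centered at geometric mean 1
  expect_true(all(is.finite(norm$sampleWeights) & norm$sampleWeights > 0))
  expect_equal(exp(mean(log(norm$sampleWeights))), 1, tolerance = 0.05)
  ## a uniformly doubled sample gets twice the scale factor of the others
  cts2 <- cts; cts2[, 2] <- base * 2
  pb2 <- pb; pb2$counts <- cts2
  norm2 <- normalizeAndWeight(pb2)
  expect_equal(norm2$scaleFactors[2] / norm2$scaleFactors[1], 2,
               tolerance = 0.05)
  ## weights are positive and finite everywhere
  expect_true(all(is.finite(norm$weights) & norm$weights > 0))
  ## all-zero sample errors
  pb3 <- pb; pb3$counts[, 1] <- 0
  expect_error(normalizeAndWeight(pb3), "all-zero")
})

test_that("the moderation formula and its limits hold", {
  expect_equal(moderatedVariance(s2 = 4, df = 4, d0 = 4, s02 = 1), 2.5)
  expect_equal(moderatedVariance(4, 4, 0, 1), 4)      # no moderation
  expect_equal(moderatedVariance(4, 4, Inf, 1), 1)    # full shrinkage
})

## A toy normalized object with unit weights: 2 cell types x 3 samples each.
toyNorm <- function(seed = 2, G = 12) {
  set.seed(seed)
  E <- matrix(rnorm(G * 6, 8), G, 6,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:6)))
  E[1:3, 4:6] <- E[1:3, 4:6] + 2
  list(E = E, weights = matrix(1, G, 6),
       sampleWeights = rep(1, 6),
       meta = data.frame(cellType = rep(c("A", "B"), each = 3),
                         animal = paste0("a", 1:6),
                         nCells = 20, detectionRate = 1))
}

test_that("d0 = 0 reproduces the ordinary t and d0 = Inf the pooled z", {
  norm <- toyNorm()
  fit0 <- fitModerated(norm, nSv = 0, d0 = 0, s02 = 1)
  tA <- fit0$table[fit0$table$contrast == "A", ]
  for (g in tA$gene) {
    tt <- t.test(norm$E[g, 1:3], norm$E[g, 4:6], var.equal = TRUE)
    expect_equal(tA$t[tA$gene == g], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tA$pValue[tA$gene == g], tt$p.value, tolerance = 1e-10)
  }
  s02 <- 1.7
  fitInf <- fitModerated(norm, nSv = 0, d0 = Inf, s02 = s02)
  tAi <- fitInf$table[fitInf$table$contrast == "A", ]
  est <- rowMeans(norm$E[, 1:3]) - rowMeans(norm$E[, 4:6])
  zExp <- est / sqrt((1 / 3 + 1 / 3) * s02)
  expect_equal(tAi$t, unname(zExp), tolerance = 1e-10)
  expect_equal(tAi$pValue, unname(2 * pnorm(-abs(zExp))), tolerance = 1e-10)
})

test_that("weighted fits agree with limma as an independent oracle", {
  skip_if_not_installed("limma")
  set.seed(3)
  G <- 20
  E <- matrix(rnorm(G * 8, 6), G, 8,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:8)))
  W <- matrix(runif(G * 8, 0.5, 2), G, 8)
  ct <- rep(c("A", "B"), each = 4)
  norm <- list(E = E, weights = W, sampleWeights = rep(1, 8),
               meta = data.frame(cellType = ct, animal = paste0("a", 1:8),
                                 nCells = 10, detectionRate = 1))
  fit <- fitModerated(norm, nSv = 0, d0 = 0, s02 = 1)
  X <- model.matrix(~ 0 + factor(ct))
  lf <- limma::lmFit(E, X, weights = W)
  estMine <- fit$table$log2FC[fit$table$contrast == "A"]
  estLimma <- lf$coefficients[, 1] - lf$coefficients[, 2]
  expect_equal(estMine, unname(estLimma), tolerance = 1e-8)
  cf <- limma::contrasts.fit(lf, c(1, -1))
  sigMine <- fit$table$log2FC[fit$table$contrast == "A"] /
    fit$table$t[fit$table$contrast == "A"]
  expect_equal(sigMine, unname(cf$sigma * cf$stdev.unscaled[, 1]),
               tolerance = 1e-8)
})

test_that("surrogate variables absorb a planted batch effect", {
  set.seed(4)
  G <- 60
  ct <- rep(c("A", "B"), each = 4)
  batch <- rep(c(0, 1), 4)
  E <- matrix(rnorm(G * 8, 8, 0.3), G, 8,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:8)))
  E <- E + outer(rnorm(G, 0, 1.5), batch)   # strong unmodeled batch
  norm <- list(E = E, weights = matrix(1, G, 8), sampleWeights = rep(1, 8),
               meta = data.frame(cellType = ct, animal = paste0("a", 1:8),
                                 nCells = 10, detectionRate = 1))
  fit <- fitModerated(norm, nSv = "auto")
  expect_gte(fit$nSv, 1)
})

test_that("adaptive FDR reduces to standard q-values and handles edge cases", {
  expect_equal(adaptiveFdr(rep(1, 10)), rep(1, 10))
  ## BH step-up on the hand example, with the null proportion fixed at 1
  expect_equal(adaptiveFdr(c(0.01, 0.02, 0.03, 0.04), pi0 = 1),
               rep(0.04, 4))
  ## constant covariate reproduces the scalar-pi0 q-values exactly
  set.seed(5)
  p <- c(runif(300), rbeta(100, 0.2, 1))
  qConst <- adaptiveFdr(p, covariate = rep(2, 400))
  qNone <- adaptiveFdr(p)
  expect_equal(qConst, qNone, tolerance = 1e-10)
  ## and equals pi0 * textbook BH
  lambdaGrid <- c(0.5, 0.6, 0.7, 0.8)
  pi0Hand <- min(1, max(0.01, mean(sapply(lambdaGrid, function(l)
    mean(p > l) / (1 - l)))))
  expect_equal(qNone, pmin(pi0Hand * bhOracle(p), 1), tolerance = 1e-10)
  expect_error(adaptiveFdr(c(0.5, 1.2)), "0, 1")
})

test_that("covariate-dependent pi0 never loses discoveries relative to BH", {
  set.seed(6)
  x <- runif(500)
  isAlt <- x > 0.7 & runif(500) < 0.5
  p <- ifelse(isAlt, rbeta(500, 0.05, 1), runif(500))
  q <- adaptiveFdr(p, covariate = x)
  bh <- p.adjust(p, "BH")
  expect_true(all(q <= bh + 1e-12))
  expect_gte(sum(q <= 0.05), sum(bh <= 0.05))
})

test_that("rank-sum statistics match exhaustive pair enumeration", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  x <- matrix(v, 1)
  rs <- striatlas:::.rankSumRows(x, 1:4, 5:8)
  ## oracle: U = number of (i, j) pairs with x_i > y_j, ties counted half
  U <- 0
  for (i in 1:4) for (j in 5:8) U <- U + (v[i] > v[j]) + 0.5 * (v[i] == v[j])
  expect_equal(unname(rs$U), U)
  ## z agrees with the tie-corrected normal approximation of wilcox.test
  wt <- suppressWarnings(wilcox.test(v[1:4], v[5:8], exact = FALSE,
                                     correct = FALSE))
  expect_equal(unname(rs$p), wt$p.value, tolerance = 1e-10)
})

test_that("relatedness counts recover planted markers and stay near zero under the null", {
  set.seed(7)
  ## 30 markers planted 4-fold in each direction; the symmetric design
  ## keeps sequencing depth exchangeable between the two populations
  G <- 500; n <- 60
  lamA <- rep(5, G); lamB <- rep(5, G)
  lamA[1:30] <- 20; lamB[31:60] <- 20
  cts <- cbind(matrix(rpois(G * n, lamA), G),
               matrix(rpois(G * n, lamB), G))
  rownames(cts) <- paste0("g", 1:G)
  labels <- rep(c("A", "B"), each = n)
  norm <- log1p(t(t(cts) / colSums(cts)) * 1e4)
  rel <- pairwiseRelatedness(norm, labels, mode = "wilcoxon")
  expect_gte(rel$counts["A", "B"], 28)
  expect_lte(rel$counts["A", "B"], 36)
  expect_gte(rel$counts["B", "A"], 28)
  expect_lte(rel$counts["B", "A"], 36)
  expect_equal(diag(rel$counts), c(A = 0, B = 0))
  ## null: two identical populations
  ctsN <- matrix(rpois(120 * 2 * n, 5), 120)
  rownames(ctsN) <- paste0("g", 1:120)
  relN <- pairwiseRelatedness(log1p(t(t(ctsN) / colSums(ctsN)) * 1e4),
                              labels, mode = "wilcoxon")
  expect_lte(max(relN$counts), 5)
})

test_that("significance sets are symmetric between pair directions", {
  set.seed(8)
  G <- 80; n <- 40
  lam <- matrix(5, G, 2); lam[1:10, 1] <- 15; lam[11:20, 2] <- 15
  cts <- cbind(matrix(rpois(G * n, lam[, 1]), G),
               matrix(rpois(G * n, lam[, 2]), G))
  rownames(cts) <- paste0("g", 1:G)
  labels <- rep(c("A", "B"), each = n)
  norm <- log1p(t(t(cts) / colSums(cts)) * 1e4)
  r1 <- pairwiseRelatedness(norm, labels, mode = "wilcoxon")
  swapped <- ifelse(labels == "A", "B", "A")
  r2 <- pairwiseRelatedness(norm, swapped, mode = "wilcoxon")
  expect_equal(r1$counts["A", "B"], r2$counts["B", "A"])
  expect_equal(r1$counts["B", "A"], r2$counts["A", "B"])
})

test_that("pseudobulk relatedness recovers markers and skips tiny labels", {
  set.seed(9)
  G <- 300
  lamA <- rep(4, G); lamA[1:20] <- 16
  mk <- function(lam, n) matrix(rpois(G * n, lam), G)
  cts <- cbind(mk(lamA, 80), mk(rep(4, G), 80))
  rownames(cts) <- paste0("g", 1:G)
  labels <- rep(c("A", "B"), each = 80)
  animals <- rep(rep(paste0("an", 1:4), each = 20), 2)
  rel <- pairwiseRelatedness(cts, labels, mode = "moderated_t",
                             animals = animals)
  expect_gte(rel$counts["A", "B"], 17)
  expect_lte(rel$counts["B", "A"], 3)
  ## a label with one aggregate is skipped and flagged
  labels2 <- labels; animals2 <- animals
  animals2[labels == "B"] <- "an9"
  rel2 <- pairwiseRelatedness(cts, labels2, mode = "moderated_t",
                              animals = animals2)
  expect_equal(rel2$skipped, "A vs B")
})

test_that("cosine similarity matches hand computation in PC space", {
  set.seed(10)
  cts <- matrix(rpois(40 * 3, 10), 40, 3,
                dimnames = list(paste0("g", 1:40), paste0("c", 1:3)))
  cs <- cosineRegionSimilarity(cts, c("R1", "R2", "R3"), nPerRegion = 1,
                               nPcs = 2, seed = 1)
  ## oracle: same normalization and PCA, cosine by explicit dot products
  ln <- log1p(t(t(cts) / colSums(cts)) * 1e4)
  pcs <- prcomp(t(ln), rank. = 2)$x
  cosHand <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(cs$similarity["R1", "R2"], cosHand(pcs[1, ], pcs[2, ]),
               tolerance = 1e-12)
  expect_equal(cs$similarity["R1", "R3"], cosHand(pcs[1, ], pcs[3, ]),
               tolerance = 1e-12)
  expect_equal(unname(diag(cs$similarity)), rep(1, 3))
})

test_that("identical and orthogonal vectors give cosine 1 and 0", {
  V <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  sims <- tcrossprod(V / sqrt(rowSums(V^2)))
  expect_equal(sims[1, 2], 1)
  expect_equal(sims[1, 3], 0)
})
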