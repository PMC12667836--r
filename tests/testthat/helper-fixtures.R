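## Shared fixtures: small panels, sections and hand-built reference objects
## used across test files. Everything is generated in code.

smallConfig <- function(seed = 1, nTypes = 3, nGenes = 30, ...) {
  simulationConfig(seed = seed, nTypes = nTypes, nGenes = nGenes, ...)
}

smallPanel <- function(...) makeReference(smallConfig(...))

## A hand-built two-type panel with disjoint support (for mixture tests).
disjointPanel <- function() {
  mu <- rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  new("ReferencePanel", geneIds = paste0("g", 1:4), typeIds = c("A", "B"),
      mu = mu, panelMask = rep(TRUE, 4),
      markerMap = list(A = c("g1", "g2"), B = c("g3", "g4")))
}

## Rectangle territory covering [0,w] x [0,h] with the given types.
rectTerritory <- function(types, density, w = 1000, h = 1000, x0 = 0, y0 = 0) {
  list(types = types,
       region = list(shape = "rect", xmin = x0, xmax = x0 + w,
                     ymin = y0, ymax = y0 + h),
       density = density)
}

## A three-class / three-subtype panel pair for hierarchical labeling:
## gene universe of 64 genes; class panel has MSN (= average of subtypes),
## Astro, Oligo; subtype panel has MSN1..MSN3. All marker blocks disjoint.
hierarchicalPanels <- function(fold = 10) {
  genes <- sprintf("g%02d", 1:64)
  block <- function(i) 8 * (i - 1) + 1:8
  mkRow <- function(markers) {
    v <- rep(1, 64); v[markers] <- fold; v / sum(v)
  }
  subMu <- rbind(mkRow(block(1)), mkRow(block(2)), mkRow(block(3)))
  glia <- rbind(mkRow(block(4)), mkRow(block(5)))
  classMu <- rbind(colMeans(subMu), glia)
  classPanel <- new("ReferencePanel", geneIds = genes,
                    typeIds = c("MSN", "Astro", "Oligo"), mu = classMu,
                    panelMask = rep(TRUE, 64),
                    markerMap = list(MSN = genes[c(block(1), block(2),
                                                   block(3))],
                                     Astro = genes[block(4)],
                                     Oligo = genes[block(5)]))
  subPanel <- new("ReferencePanel", geneIds = genes,
                  typeIds = paste0("MSN", 1:3), mu = subMu,
                  panelMask = rep(TRUE, 64),
                  markerMap = list(MSN1 = genes[block(1)],
                                   MSN2 = genes[block(2)],
                                   MSN3 = genes[block(3)]))
  fullPanel <- new("ReferencePanel", geneIds = genes,
                   typeIds = c(paste0("MSN", 1:3), "Astro", "Oligo"),
                   mu = rbind(subMu, glia), panelMask = rep(TRUE, 64),
                   markerMap = list(MSN1 = genes[block(1)],
                                    MSN2 = genes[block(2)],
                                    MSN3 = genes[block(3)],
                                    Astro = genes[block(4)],
                                    Oligo = genes[block(5)]))
  list(class = classPanel, subtype = subPanel, full = fullPanel)
}

## Cells drawn from arbitrary profiles at fixed depth (multinomial or NB).
cellsFromProfiles <- function(panel, types, depth = 300, alpha = 0.1,
                              seed = 1) {
  withSeed(seed, {
    mu <- panel@mu[match(types, panel@typeIds), , drop = FALSE] * depth
    cts <- matrix(rcounts(length(mu), as.vector(t(mu)), alpha),
                  nrow = ncol(mu))
  })
  rownames(cts) <- panel@geneIds
  colnames(cts) <- paste0("c", seq_along(types))
  cts
}

withSeed <- striatlas:::withSeed
rcounts <- striatlas:::rcounts

## Brute-force Otsu scan used as the independent oracle: recomputes the
## histogram and between-class variance edge by edge with plain loops.
otsuOracle <- function(coords, nBins = 128) {
  breaks <- seq(min(coords), max(coords), length.out = nBins + 1)
  bin <- findInterval(coords, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mids <- (breaks[-1] + breaks[-(nBins + 1)]) / 2
  best <- -Inf; bestEdges <- numeric()
  for (j in 1:(nBins - 1)) {
    left <- bin <= j
    w0 <- sum(left); w1 <- length(coords) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(mids[bin[left]]) / w0
    mu1 <- sum(mids[bin[!left]]) / w1
    bc <- (w0 / length(coords)) * (w1 / length(coords)) * (mu0 - mu1)^2
    if (!is.finite(best) || bc > best + 1e-12 * abs(best)) {
      best <- bc; bestEdges <- breaks[j + 1]
    } else if (abs(bc - best) <= 1e-12 * abs(best)) {
      bestEdges <- c(bestEdges, breaks[j + 1])
    }
  }
  bestEdges[which.min(abs(bestEdges - median(coords)))]
}

## Textbook BH step-up oracle.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}
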