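## Synthetic-data generator: reference panels, reference-like cells, spatial
## sections with territorial layouts and abundance gradients, expression
## discontinuities, and rostro-caudal section series. Every generated cell
## carries its ground-truth type so downstream recovery tests are closed.

#' Build a SpatialCellTable
#'
#' The package's container for spatially resolved cells is a
#' \link[SingleCellExperiment]{SingleCellExperiment} with a \code{counts}
#' assay (genes x cells, sparse) and the column metadata the analysis
#' requires: \code{x_um}, \code{y_um}, \code{section_id}, \code{rc_level_mm}
#' (signed mm from the anterior commissure, rostral positive),
#' \code{animal_id}, \code{species_id}, \code{true_type} (ground truth,
#' synthetic data only) and \code{assigned_label}.
#'
#' @param counts genes x cells matrix (coerced to sparse).
#' @param meta data.frame with one row per cell; missing standard columns are
#'   filled with NA.
#' @param metadata optional list stored as object metadata (e.g. seed).
#' @return a \code{SingleCellExperiment}
#' @export
SpatialCellTable <- function(counts, meta, metadata = list()) {
  counts <- methods::as(Matrix::Matrix(as.matrix(counts) * 1, sparse = TRUE),
                        "CsparseMatrix")
  std <- c("cell_id", "x_um", "y_um", "section_id", "rc_level_mm",
           "animal_id", "species_id", "true_type", "assigned_label")
  for (col in std) if (is.null(meta[[col]])) meta[[col]] <- rep(NA, nrow(meta))
  if (nrow(meta) > 0 && all(is.na(meta$cell_id)))
    meta$cell_id <- paste0("cell", seq_len(nrow(meta)))
  colnames(counts) <- meta$cell_id
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta, row.names = meta$cell_id))
  S4Vectors::metadata(sce) <- metadata
  validateSpatialCellTable(sce)
  sce
}

#' Validate a SpatialCellTable
#'
#' Checks the container invariants: nonnegative integer counts, finite
#' coordinates for spatially placed cells, and a constant rostro-caudal
#' level within each section.
#'
#' @param sce a \code{SingleCellExperiment} from [SpatialCellTable()]
#' @return invisibly TRUE; errors on violation
#' @export
validateSpatialCellTable <- function(sce) {
  cts <- SummarizedExperiment::assay(sce, "counts")
  if (length(cts@x)) {
    stopifnot2(min(cts@x) >= 0, "counts must be nonnegative")
    stopifnot2(all(cts@x == round(cts@x)), "counts must be integers")
  }
  cd <- SummarizedExperiment::colData(sce)
  xy <- cbind(cd$x_um, cd$y_um)
  placed <- !is.na(xy[, 1])
  stopifnot2(all(is.finite(xy[placed, ])), "coordinates must be finite")
  if (!all(is.na(cd$section_id))) {
    bysec <- split(cd$rc_level_mm, cd$section_id)
    ok <- vapply(bysec, function(v) length(unique(v[!is.na(v)])) <= 1, TRUE)
    stopifnot2(all(ok), "rc_level_mm must be constant within a section")
  }
  invisible(TRUE)
}

#' Generate a reference expression panel
#'
#' Constructs cell-type profiles with disjoint marker blocks: every gene has
#' baseline relative expression 1 and each type's \code{markersPerType}
#' marker genes are elevated \code{markerFold}-fold; rows are then
#' normalized to sum to one. The construction is deterministic given the
#' configuration, and marker blocks must fit disjointly into the panel.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a \linkS4class{ReferencePanel}
#' @examples
#' panel <- makeReference(simulationConfig(seed = 1, nTypes = 3, nGenes = 30))
#' rowSums(profileMatrix(panel))
#' @export
makeReference <- function(config) {
  methods::validObject(config)
  T <- config@nTypes; G <- config@nGenes; m <- config@markersPerType
  stopifnot2(T * m <= G,
             "marker blocks cannot be disjoint: nTypes * markersPerType > nGenes")
  genes <- sprintf("G%03d", seq_len(G))
  types <- paste0("T", seq_len(T))
  mu <- matrix(1, T, G)
  markerMap <- vector("list", T); names(markerMap) <- types
  for (t in seq_len(T)) {
    idx <- ((t - 1L) * m + 1L):(t * m)
    mu[t, idx] <- config@markerFold
    markerMap[[t]] <- genes[idx]
  }
  mu <- mu / rowSums(mu)
  new("ReferencePanel", geneIds = genes, typeIds = types, mu = mu,
      panelMask = rep(TRUE, G), markerMap = markerMap)
}

## Expected count rates for cells of given types: library size x per-type
## profile, optionally distorted by per-gene platform factors (renormalized
## so the expected depth is preserved).
.expectedRates <- function(panel, types, libSizes, platformFactors = NULL) {
  P <- panel@mu
  if (!is.null(platformFactors)) {
    P <- sweep(P, 2, platformFactors, "*")
    P <- P / rowSums(P)
  }
  P[match(types, panel@typeIds), , drop = FALSE] * libSizes
}

## Sample an NB count matrix (genes x cells) given per-cell expected rates.
.sampleCounts <- function(rates, alpha) {
  n <- length(rates)
  cts <- rcounts(n, as.vector(t(rates)), alpha)
  matrix(cts, nrow = ncol(rates), ncol = nrow(rates))
}

#' Simulate dissociated reference-like cells
#'
#' Draws \code{nPerType} cells per reference type with negative-binomial
#' counts of mean \code{librarySize x mu[type, ]} — an snRNA-seq-like
#' reference with no spatial coordinates. The ground-truth type is recorded
#' in \code{true_type}.
#'
#' @param panel a \linkS4class{ReferencePanel}
#' @param nPerType cells per type (0 gives an empty table)
#' @param config a \linkS4class{SimulationConfig}
#' @param seed optional seed override (defaults to a substream of
#'   \code{config@seed})
#' @return a SpatialCellTable with NA coordinates
#' @export
simulateReferenceCells <- function(panel, nPerType, config, seed = NULL) {
  stopifnot2(nPerType >= 0, "nPerType must be >= 0")
  if (is.null(seed)) seed <- subSeed(config@seed, "refcells")
  types <- rep(panel@typeIds, each = nPerType)
  n <- length(types)
  withSeed(seed, {
    lib <- rlibsize(n, config@librarySizeMean, config@librarySizeDispersion)
    rates <- .expectedRates(panel, types, lib)
    cts <- if (n) .sampleCounts(rates, config@nbDispersion) else
      matrix(0L, length(panel@geneIds), 0L)
  })
  rownames(cts) <- panel@geneIds
  meta <- data.frame(cell_id = if (n) paste0("ref", seq_len(n)) else character(),
                     true_type = types, stringsAsFactors = FALSE)
  SpatialCellTable(cts, meta, metadata = list(seed = seed))
}

## ---- spatial regions ------------------------------------------------------
## Territories use axis-aligned rectangles, discs, and half-planes (clipped
## to a declared bounding box). Each returns area and a uniform sampler.

.regionArea <- function(region) {
  switch(region$shape,
    rect = (region$xmax - region$xmin) * (region$ymax - region$ymin),
    disc = pi * region$r^2,
    halfplane = {
      bb <- region$bbox
      w <- if (region$axis == "x") {
        if (region$side == "right") bb$xmax - max(bb$xmin, region$at)
        else min(bb$xmax, region$at) - bb$xmin
      } else {
        if (region$side == "right") bb$ymax - max(bb$ymin, region$at)
        else min(bb$ymax, region$at) - bb$ymin
      }
      max(w, 0) * if (region$axis == "x") (bb$ymax - bb$ymin) else
        (bb$xmax - bb$xmin)
    },
    stop("unknown region shape: ", region$shape))
}

.regionSample <- function(region, n) {
  if (n == 0) return(cbind(x = numeric(), y = numeric()))
  switch(region$shape,
    rect = cbind(x = runif(n, region$xmin, region$xmax),
                 y = runif(n, region$ymin, region$ymax)),
    disc = {
      r <- region$r * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
      cbind(x = region$cx + r * cos(th), y = region$cy + r * sin(th))
    },
    halfplane = {
      bb <- region$bbox
      if (region$axis == "x") {
        lo <- if (region$side == "right") max(bb$xmin, region$at) else bb$xmin
        hi <- if (region$side == "right") bb$xmax else min(bb$xmax, region$at)
        cbind(x = runif(n, lo, hi), y = runif(n, bb$ymin, bb$ymax))
      } else {
        lo <- if (region$side == "right") max(bb$ymin, region$at) else bb$ymin
        hi <- if (region$side == "right") bb$ymax else min(bb$ymax, region$at)
        cbind(x = runif(n, bb$xmin, bb$xmax), y = runif(n, lo, hi))
      }
    })
}

## Type mixing proportions at a rostro-caudal position: multinomial logit
## over the territory's types using gradientSpec plus random intercepts.
.typeProbs <- function(types, gradientSpec, rcIndex,
                       animalEff = NULL, speciesEff = NULL) {
  eta <- vapply(types, function(t) {
    row <- gradientSpec[gradientSpec$type == t, , drop = FALSE]
    e <- if (nrow(row)) row$intercept[1] + row$slope[1] * rcIndex else 0
    e + (animalEff[t] %||% 0) + (speciesEff[t] %||% 0)
  }, 0)
  p <- exp(eta - max(eta))
  p / sum(p)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0) return(b)
  if (length(a) == 1 && is.atomic(a) && is.na(a)) return(b)
  a
}

#' Per-gene platform factors of a configuration
#'
#' Log-normal multipliers (sd \code{platformSd}) emulating reference-versus-
#' spatial platform differences; drawn once per configuration so all
#' sections of a simulation share them.
#'
#' @param panel a \linkS4class{ReferencePanel}
#' @param config a \linkS4class{SimulationConfig}
#' @return named numeric vector over panel genes
#' @export
configPlatformFactors <- function(panel, config) {
  g <- withSeed(subSeed(config@seed, "platform"),
                rlnorm(length(panel@geneIds), 0, config@platformSd))
  names(g) <- panel@geneIds
  g
}

#' Generate one spatial section
#'
#' Places cells by a spatial Poisson process within each territory (expected
#' count = density x area), assigns ground-truth types by the territory's
#' type mix at the section's rostro-caudal position, and samples counts as
#' negative binomial with the configuration's per-gene platform factors
#' applied. Territory layouts use simple geometry (rectangles, discs,
#' half-planes) to emulate striosome islands, matrix background, and
#' medial-lateral bands.
#'
#' @param panel a \linkS4class{ReferencePanel}
#' @param config a \linkS4class{SimulationConfig}; its \code{territorySpec}
#'   entries are \code{list(types=, region=, density=)} with density in
#'   cells per square micron.
#' @param rcLevelMm signed rostro-caudal level (mm from AC, rostral positive)
#' @param sectionId,animalId,speciesId identifiers recorded per cell
#' @param rcIndex rostro-caudal progression index used by abundance
#'   gradients (0 = most rostral section; defaults to \code{-rcLevelMm / 2},
#'   one unit per 2 mm step)
#' @param animalEff,speciesEff optional named per-type random intercepts
#' @param seed optional seed override
#' @return a SpatialCellTable (empty, with a warning, if all densities are 0)
#' @export
makeSection <- function(panel, config, rcLevelMm, sectionId = "S1",
                        animalId = "A1", speciesId = "Sp1",
                        rcIndex = NULL, animalEff = NULL, speciesEff = NULL,
                        seed = NULL) {
  methods::validObject(config)
  if (is.null(rcIndex)) rcIndex <- -rcLevelMm / 2
  if (is.null(seed)) seed <- subSeed(config@seed, paste0("section:", sectionId))
  gamma <- configPlatformFactors(panel, config)
  withSeed(seed, {
    xs <- ys <- numeric(); types <- character()
    for (terr in config@territorySpec) {
      area <- .regionArea(terr$region)
      n <- rpois(1, terr$density * area)
      if (n == 0) next
      xy <- .regionSample(terr$region, n)
      pr <- .typeProbs(terr$types, config@gradientSpec, rcIndex,
                      animalEff, speciesEff)
      tt <- terr$types[sample.int(length(terr$types), n, replace = TRUE,
                                  prob = pr)]
      xs <- c(xs, xy[, "x"]); ys <- c(ys, xy[, "y"]); types <- c(types, tt)
    }
    n <- length(types)
    if (n == 0) {
      warning("section '", sectionId, "' is empty (all densities 0)")
      cts <- matrix(0L, length(panel@geneIds), 0L)
    } else {
      lib <- rlibsize(n, config@librarySizeMean, config@librarySizeDispersion)
      rates <- .expectedRates(panel, types, lib, platformFactors = gamma)
      cts <- .sampleCounts(rates, config@nbDispersion)
    }
  })
  rownames(cts) <- panel@geneIds
  meta <- data.frame(
    cell_id = if (n) paste0(sectionId, "_c", seq_len(n)) else character(),
    x_um = xs, y_um = ys, section_id = rep(sectionId, n),
    rc_level_mm = rep(rcLevelMm, n), animal_id = rep(animalId, n),
    species_id = rep(speciesId, n), true_type = types,
    stringsAsFactors = FALSE)
  SpatialCellTable(cts, meta,
                   metadata = list(seed = seed, platformFactors = gamma,
                                   rcIndex = rcIndex))
}

#' Inject an expression discontinuity into a section
#'
#' Overwrites one gene's counts so its expected expression along the chosen
#' axis is \code{intercept + slope * (axis - boundary) + jump *
#' 1[axis > boundary]} plus Gaussian rate noise, realized as negative-
#' binomial counts. The ground-truth jump is stored in the object metadata,
#' closing the loop for boundary-recovery tests. \code{jump = 0} gives the
#' pure-gradient null case.
#'
#' @param section a SpatialCellTable with coordinates
#' @param gene panel gene to overwrite
#' @param axis "x" or "y"
#' @param boundary axis value of the step (must lie in the coordinate range)
#' @param jump,slope,noiseSd,intercept rate-scale parameters
#' @param alpha NB dispersion (defaults 0.1)
#' @param seed optional seed override
#' @return the modified SpatialCellTable
#' @export
injectDiscontinuity <- function(section, gene, axis = c("x", "y"), boundary,
                                jump, slope = 0, noiseSd = 0, intercept = 5,
                                alpha = 0.1, seed = NULL) {
  axis <- match.arg(axis)
  stopifnot2(gene %in% rownames(section), "gene must be on the panel")
  ax <- if (axis == "x") section$x_um else section$y_um
  stopifnot2(boundary >= min(ax) && boundary <= max(ax),
             "boundary lies outside the coordinate range")
  if (is.null(seed))
    seed <- subSeed(S4Vectors::metadata(section)$seed %||% 0,
                    paste0("disc:", gene))
  n <- ncol(section)
  withSeed(seed, {
    mu <- intercept + slope * (ax - boundary) + jump * (ax > boundary)
    if (noiseSd > 0) mu <- mu + rnorm(n, 0, noiseSd)
    newCounts <- rcounts(n, mu, alpha)
  })
  cts <- SummarizedExperiment::assay(section, "counts")
  cts[gene, ] <- newCounts
  SummarizedExperiment::assay(section, "counts") <- cts
  md <- S4Vectors::metadata(section)
  md$discontinuities <- c(md$discontinuities, list(list(
    gene = gene, axis = axis, boundary = boundary, jump = jump,
    slope = slope, noiseSd = noiseSd, intercept = intercept)))
  S4Vectors::metadata(section) <- md
  section
}

#' Generate a rostro-caudal section series
#'
#' Builds one section per animal per level (optionally several), with
#' per-animal and per-species random intercepts on the abundance-gradient
#' scale drawn once and reused across levels. Animals are assigned to
#' species round-robin. The rostro-caudal index passed to the gradient is
#' the rank of the level in rostral-to-caudal order (0 = most rostral), the
#' same ordinal coding [lmmFit()] uses.
#'
#' @param panel a \linkS4class{ReferencePanel}
#' @param config a \linkS4class{SimulationConfig}; needs a non-empty
#'   \code{territorySpec}
#' @param levels rostro-caudal levels in mm (e.g. \code{c(2, 0, -2, -4, -8)})
#' @param nAnimals,nSpecies series design
#' @param sectionsPerLevel sections per animal per level
#' @return list of SpatialCellTables
#' @export
makeRCSeries <- function(panel, config, levels, nAnimals = 2, nSpecies = 1,
                         sectionsPerLevel = 1) {
  stopifnot2(length(levels) >= 2, "need >= 2 levels")
  gs <- config@gradientSpec
  animals <- paste0("A", seq_len(nAnimals))
  species <- paste0("Sp", seq_len(nSpecies))
  speciesOf <- setNames(rep_len(species, nAnimals), animals)
  effs <- withSeed(subSeed(config@seed, "rcseries"), {
    aEff <- lapply(animals, function(a)
      setNames(rnorm(nrow(gs), 0, gs$animalSd), gs$type))
    sEff <- lapply(species, function(s)
      setNames(rnorm(nrow(gs), 0, gs$speciesSd), gs$type))
    list(a = setNames(aEff, animals), s = setNames(sEff, species))
  })
  ord <- order(levels, decreasing = TRUE)   # rostral first
  rcIndex <- setNames(seq_along(levels) - 1, levels[ord])
  out <- list()
  for (a in animals) for (li in seq_along(ord)) for (r in seq_len(sectionsPerLevel)) {
    lev <- levels[ord][li]
    sid <- sprintf("%s_L%g_r%d", a, lev, r)
    out[[sid]] <- makeSection(panel, config, rcLevelMm = lev, sectionId = sid,
                              animalId = a, speciesId = speciesOf[a],
                              rcIndex = rcIndex[[as.character(lev)]],
                              animalEff = effs$a[[a]],
                              speciesEff = effs$s[[speciesOf[a]]])
  }
  out
}
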