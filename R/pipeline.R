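## End-to-end orchestration from a single configuration: stages run in
## dependency order, every stage draws from its own seed substream (hashed
## from the stage name, so inserting a stage does not perturb the draws of
## the others) and writes a manifest with parameters, seed, and output
## checksums.

.stageManifest <- function(dir, stage, params, seed, files) {
  manifest <- list(stage = stage, params = params, seed = seed,
                   outputs = lapply(files, function(f)
                     list(path = f, md5 = unname(tools::md5sum(f)))))
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order
#' (\code{simulate -> label -> niche -> rdd / gradients}), writing each
#' stage's outputs and a JSON manifest (inputs, parameters, seed, output
#' checksums) under \code{outDir}. Reruns with an identical configuration
#' are byte-identical for deterministic stages. The configuration is a YAML
#' or JSON file (or an equivalent list) with a global \code{seed}, a
#' \code{stages} vector, and optional per-stage parameter blocks.
#'
#' Supported stages and their parameter blocks:
#' \describe{
#'   \item{simulate}{\code{nTypes}, \code{nGenes}, \code{levels} (rc levels
#'     in mm), \code{nAnimals}, \code{nSpecies}, \code{density},
#'     \code{width}, \code{height}, optional \code{discontinuity} (gene /
#'     axis / boundary / jump / slope / noiseSd).}
#'   \item{label}{\code{threshold}.}
#'   \item{niche}{\code{k}, \code{nClusters}.}
#'   \item{rdd}{\code{gene}, \code{types}, \code{axis}.}
#'   \item{gradients}{\code{group}, \code{type} (tested type),
#'     \code{pair}.}
#' }
#'
#' @param config path to a YAML/JSON config file, or a list
#' @param outDir output directory
#' @return named list of manifest paths (invisibly also written to disk)
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stages <- config$stages
  order <- c("simulate", "label", "niche", "rdd", "gradients")
  stages <- order[order %in% stages]
  manifests <- list()
  state <- new.env()

  for (stage in stages) {
    prm <- config[[stage]] %||% list()
    sseed <- subSeed(seed, stage)
    res <- tryCatch(
      switch(stage,
        simulate = .stageSimulate(prm, sseed, outDir, state),
        label = .stageLabel(prm, outDir, state),
        niche = .stageNiche(prm, sseed, outDir, state),
        rdd = .stageRdd(prm, outDir, state),
        gradients = .stageGradients(prm, outDir, state)),
      error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    manifests[[stage]] <- .stageManifest(outDir, stage, prm, sseed, res)
  }
  manifests
}

.stageSimulate <- function(prm, sseed, outDir, state) {
  nTypes <- prm$nTypes %||% 5L
  nGenes <- prm$nGenes %||% 60L
  width <- prm$width %||% 1000
  height <- prm$height %||% 1000
  density <- prm$density %||% 0.002
  cfg <- simulationConfig(
    seed = sseed, nTypes = nTypes, nGenes = nGenes,
    territorySpec = list(list(
      types = paste0("T", seq_len(nTypes)),
      region = list(shape = "rect", xmin = 0, xmax = width,
                    ymin = 0, ymax = height),
      density = density)))
  panel <- makeReference(cfg)
  levels <- prm$levels %||% c(2, 0, -2, -4, -8)
  sections <- makeRCSeries(panel, cfg, levels = levels,
                           nAnimals = prm$nAnimals %||% 2L,
                           nSpecies = prm$nSpecies %||% 1L)
  if (!is.null(prm$discontinuity)) {
    d <- prm$discontinuity
    sections[[1]] <- injectDiscontinuity(
      sections[[1]], gene = d$gene, axis = d$axis %||% "x",
      boundary = d$boundary, jump = d$jump, slope = d$slope %||% 0,
      noiseSd = d$noiseSd %||% 0)
  }
  state$panel <- panel; state$config <- cfg; state$sections <- sections
  files <- character()
  for (nm in names(sections)) {
    f <- writeSpatialCellTable(sections[[nm]],
                               file.path(outDir, "sections", nm))
    files <- c(files, f)
  }
  pf <- file.path(outDir, "reference_panel.tsv")
  writeReferencePanel(panel, pf)
  c(files, pf)
}

.stageLabel <- function(prm, outDir, state) {
  stopifnot2(!is.null(state$sections), "label stage needs simulate outputs")
  threshold <- prm$threshold %||% 0.5
  files <- character()
  for (nm in names(state$sections)) {
    s <- state$sections[[nm]]
    cts <- SummarizedExperiment::assay(s, "counts")
    W <- decomposeCells(cts, state$panel)
    md <- classifyMode(cts, state$panel)
    a <- assignLabel(W, md$mode, threshold)
    s$assigned_label <- a$assigned_label
    state$sections[[nm]] <- s
    top3 <- t(apply(W, 1, function(w) {
      o <- order(w, decreasing = TRUE)[1:3]
      c(paste(colnames(W)[o], collapse = ","),
        paste(signif(w[o], 4), collapse = ","))
    }))
    out <- data.frame(cell_id = colnames(s), mode = md$mode,
                      assigned_label = a$assigned_label,
                      top3_types = top3[, 1], top3_weights = top3[, 2])
    f <- file.path(outDir, paste0("labels_", nm, ".tsv"))
    write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  files
}

.stageNiche <- function(prm, sseed, outDir, state) {
  stopifnot2(!is.null(state$sections), "niche stage needs labeled sections")
  s <- state$sections[[1]]
  labels <- s$assigned_label %||% s$true_type
  na <- nicheAssay(s, k = prm$k %||% 30, nClusters = prm$nClusters %||% 30,
                   labelCol = if (is.null(s$assigned_label)) "true_type"
                              else "assigned_label",
                   seed = sseed, msnLabels = prm$msnLabels %||% NULL)
  out <- data.frame(cell_id = colnames(s),
                    niche_id = nicheOfCell(na$model),
                    in_striatum = na$inStriatum)
  f <- file.path(outDir, "niches.tsv")
  write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  fc <- file.path(outDir, "niche_centroids.tsv")
  write.table(data.frame(niche = seq_len(nrow(na$model@centroids)),
                         na$model@centroids, check.names = FALSE),
              fc, sep = "\t", quote = FALSE, row.names = FALSE)
  c(f, fc)
}

.stageRdd <- function(prm, outDir, state) {
  stopifnot2(!is.null(state$sections), "rdd stage needs sections")
  s <- state$sections[[1]]
  labelCol <- if (is.null(s$assigned_label)) "true_type" else "assigned_label"
  res <- rddPipeline(s, gene = prm$gene,
                     types = prm$types %||% unique(s$true_type)[1:2],
                     mode = prm$axis %||% "axis_x", labelCol = labelCol)
  f <- file.path(outDir, "rdd_result.tsv")
  write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
  fj <- file.path(outDir, "rdd_result.json")
  jsonlite::write_json(as.list(res), fj, auto_unbox = TRUE, digits = NA)
  c(f, fj)
}

.stageGradients <- function(prm, outDir, state) {
  stopifnot2(!is.null(state$sections), "gradients stage needs sections")
  useAssigned <- !is.null(state$sections[[1]]$assigned_label)
  labelCol <- if (useAssigned) "assigned_label" else "true_type"
  group <- prm$group %||% unique(state$sections[[1]]$true_type)
  ag <- abundanceGradient(state$sections, group = group,
                          pair = prm$pair %||% NULL, labelCol = labelCol)
  f <- file.path(outDir, "gradient_persection.tsv")
  write.table(ag$perSection, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- f
  if (!is.null(prm$type)) {
    gt <- gradientTest(state$sections, type = prm$type, group = group,
                       labelCol = labelCol)
    fj <- file.path(outDir, "gradient_lmm.json")
    jsonlite::write_json(gt[c("beta", "seBeta", "pValue",
                              "randomInterceptSd", "residualSd", "nObs",
                              "nGroups")],
                         fj, auto_unbox = TRUE, digits = NA)
    files <- c(files, fj)
  }
  files
}
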