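## Plain-text interchange: MatrixMarket counts with gene/cell TSVs for cell
## tables, wide TSV for reference panels, TSVs for labels and enrichment
## inputs. The generator seed is echoed into every metadata header.

#' Write a SpatialCellTable to disk
#'
#' Writes \code{matrix.mtx} (MatrixMarket, genes x cells),
#' \code{genes.tsv}, and \code{cells.tsv} (all standard metadata columns;
#' the generating seed echoed in a \code{# seed:} header line).
#'
#' @param sce a SpatialCellTable
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeSpatialCellTable <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(SummarizedExperiment::assay(sce, "counts"), mtx)
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cells <- file.path(dir, "cells.tsv")
  seed <- S4Vectors::metadata(sce)$seed
  con <- file(cells, "w")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.table(cd, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(mtx, file.path(dir, "genes.tsv"), cells))
}

#' Read a SpatialCellTable written by [writeSpatialCellTable()]
#'
#' @param dir directory containing matrix.mtx / genes.tsv / cells.tsv
#' @return a SpatialCellTable
#' @export
readSpatialCellTable <- function(dir) {
  cts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                     "CsparseMatrix")
  rownames(cts) <- readLines(file.path(dir, "genes.tsv"))
  meta <- read.delim(file.path(dir, "cells.tsv"), comment.char = "#",
                     stringsAsFactors = FALSE)
  hdr <- readLines(file.path(dir, "cells.tsv"), n = 1)
  seed <- if (grepl("^# seed:", hdr)) as.integer(sub("^# seed: *", "", hdr))
          else NULL
  SpatialCellTable(cts, meta, metadata = list(seed = seed))
}

#' Write / read a reference panel as TSV
#'
#' Wide layout: one row per cell type, one column per gene, plus
#' \code{type} and \code{markers} (comma-separated) columns; genes off the
#' spatial panel are marked in a \code{# off_panel:} header.
#'
#' @param panel a \linkS4class{ReferencePanel}
#' @param path TSV path
#' @return invisibly, the path
#' @export
writeReferencePanel <- function(panel, path) {
  con <- file(path, "w")
  off <- panel@geneIds[!panel@panelMask]
  writeLines(paste0("# off_panel: ", paste(off, collapse = ",")), con)
  df <- data.frame(type = panel@typeIds,
                   markers = vapply(panel@markerMap[panel@typeIds],
                                    paste, "", collapse = ","),
                   panel@mu, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-(1:2)] <- panel@geneIds
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeReferencePanel
#' @export
readReferencePanel <- function(path) {
  hdr <- readLines(path, n = 1)
  off <- strsplit(sub("^# off_panel: *", "", hdr), ",")[[1]]
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  genes <- setdiff(colnames(df), c("type", "markers"))
  mu <- as.matrix(df[, genes])
  rownames(mu) <- df$type
  new("ReferencePanel", geneIds = genes, typeIds = df$type, mu = mu,
      panelMask = !(genes %in% off),
      markerMap = setNames(strsplit(df$markers, ","), df$type))
}
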