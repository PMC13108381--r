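## Import/export of the standard on-disk formats: MatrixMarket counts,
## STAR SJ.out.tab junction text, calibrated TIFF images with YAML
## sidecars, and JSON ground truth.

#' @importFrom Matrix readMM writeMM sparseMatrix
#' @importFrom utils read.table write.table
NULL

#' Write a CellCounts object as MatrixMarket + TSV sidecars
#'
#' Produces `<prefix>.mtx` (sparse counts), `<prefix>.genes.tsv`,
#' `<prefix>.barcodes.tsv` and `<prefix>.labels.tsv` (cell, subclass,
#' total).
#'
#' @param x a [CellCounts].
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
writeCellCounts <- function(x, prefix) {
  stopifnot(is(x, "CellCounts"))
  cts <- assay(x, "counts")
  writeMM(as(Matrix::Matrix(cts, sparse = TRUE), "generalMatrix"),
          paste0(prefix, ".mtx"))
  writeLines(rownames(cts), paste0(prefix, ".genes.tsv"))
  writeLines(colnames(cts), paste0(prefix, ".barcodes.tsv"))
  write.table(data.frame(cell = colnames(cts),
                         subclass = subclassLabels(x),
                         total = cellTotals(x)),
              paste0(prefix, ".labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a CellCounts object written by [writeCellCounts()]
#'
#' Also accepts a dense TSV (genes in rows) via `dense = TRUE`.
#'
#' @param prefix path prefix (or dense TSV path when `dense = TRUE`).
#' @param dense read a dense genes x cells TSV instead of MTX.
#' @param labels optional path to a labels TSV (columns cell,
#'   subclass[, total]).
#' @return a [CellCounts].
#' @export
readCellCounts <- function(prefix, dense = FALSE, labels = NULL) {
  if (dense) {
    m <- as.matrix(read.table(prefix, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
  } else {
    m <- as.matrix(readMM(paste0(prefix, ".mtx")))
    rownames(m) <- readLines(paste0(prefix, ".genes.tsv"))
    colnames(m) <- readLines(paste0(prefix, ".barcodes.tsv"))
    if (is.null(labels) && file.exists(paste0(prefix, ".labels.tsv")))
      labels <- paste0(prefix, ".labels.tsv")
  }
  subclass <- NULL; total <- NULL
  if (!is.null(labels)) {
    lab <- read.table(labels, sep = "\t", header = TRUE)
    idx <- match(colnames(m), lab[[1]])
    subclass <- lab$subclass[idx]
    if ("total" %in% names(lab)) total <- lab$total[idx]
  }
  CellCounts(m, subclass = subclass, total = total)
}

#' Write junction counts as a long-format TSV
#'
#' One row per (cell, event): columns `cell`, `gene`, `event`, `I`,
#' `E`.
#'
#' @param jc a [JunctionCounts].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeJunctionTable <- function(jc, path) {
  stopifnot(is(jc, "JunctionCounts"))
  I <- assay(jc, "I"); E <- assay(jc, "E")
  long <- data.frame(
    cell = rep(colnames(jc), each = nrow(jc)),
    gene = rep(rowData(jc)$gene, ncol(jc)),
    event = rep(rowData(jc)$event, ncol(jc)),
    I = as.vector(I), E = as.vector(E))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format junction TSV written by [writeJunctionTable()]
#'
#' @param path input file.
#' @param variantGroup optional named vector mapping event labels to
#'   variant groups.
#' @return a [JunctionCounts].
#' @export
readJunctionTable <- function(path, variantGroup = NULL) {
  long <- read.table(path, sep = "\t", header = TRUE)
  cells <- unique(long$cell)
  ev <- unique(long[, c("gene", "event")])
  key <- paste(ev$gene, ev$event)
  I <- E <- matrix(0, nrow(ev), length(cells),
                   dimnames = list(NULL, cells))
  ri <- match(paste(long$gene, long$event), key)
  ci <- match(long$cell, cells)
  I[cbind(ri, ci)] <- long$I
  E[cbind(ri, ci)] <- long$E
  vg <- if (is.null(variantGroup)) NULL
        else unname(variantGroup[ev$event])
  JunctionCounts(I, E, gene = ev$gene, event = ev$event,
                 variantGroup = vg)
}

#' Write a calibrated image as TIFF with a YAML calibration sidecar
#'
#' Requires the suggested packages `tiff` and `yaml`.
#'
#' @param image a [VesselImage].
#' @param path output TIFF path; the sidecar is `<path>.yaml`.
#' @return the path, invisibly.
#' @export
writeCalibratedTIFF <- function(image, path) {
  stopifnot(is(image, "VesselImage"))
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("yaml", quietly = TRUE))
    stop("packages 'tiff' and 'yaml' are required for TIFF export")
  m <- image@pixels
  r <- range(m)
  if (diff(r) > 0) m <- (m - r[1]) / diff(r)
  tiff::writeTIFF(m, path)
  yaml::write_yaml(list(pixel_size_um = image@pixelSize,
                        intensity_range = as.numeric(r)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a calibrated TIFF written by [writeCalibratedTIFF()]
#'
#' @param path TIFF path with a `<path>.yaml` sidecar.
#' @return a [VesselImage].
#' @export
readCalibratedTIFF <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("yaml", quietly = TRUE))
    stop("packages 'tiff' and 'yaml' are required for TIFF import")
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  m <- tiff::readTIFF(path)
  if (!is.null(meta$intensity_range)) {
    r <- meta$intensity_range
    m <- m * (r[2] - r[1]) + r[1]
  }
  VesselImage(m, meta$pixel_size_um)
}
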