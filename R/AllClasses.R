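#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowData
NULL

## ---------------------------------------------------------------------------
## Expression containers
## ---------------------------------------------------------------------------

#' CellCounts: genes x cells raw count matrix with cell metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' `"counts"` (non-negative integers, genes in rows, cells in columns)
#' plus per-cell metadata columns `subclass` (character label, possibly
#' `"unassigned"`), `total` (total mapped reads; defaults to the column
#' sum) and `genesDetected` (genes with at least one read).
#'
#' @export
setClass("CellCounts", contains = "SummarizedExperiment")

setValidity("CellCounts", function(object) {
  msg <- NULL
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  }
  for (col in c("subclass", "total", "genesDetected"))
    if (!col %in% names(colData(object)))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if (is.null(msg)) TRUE else msg
})

#' Construct a CellCounts object
#'
#' @param counts genes x cells matrix (dense or `Matrix::dgCMatrix`) of
#'   non-negative integer counts.
#' @param subclass character vector of per-cell subclass labels; missing
#'   labels become `"unassigned"`.
#' @param total optional externally supplied per-cell total mapped
#'   reads. Defaults to the column sums of `counts` (the usual case when
#'   no alignment summary is available).
#' @return a [CellCounts] object.
#' @examples
#' m <- matrix(rpois(20, 5), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' cc <- CellCounts(m, subclass = rep(c("A", "B"), c(2, 3)))
#' cellTotals(cc)
#' @export
CellCounts <- function(counts, subclass = NULL, total = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(subclass)) subclass <- rep("unassigned", ncol(counts))
  subclass <- as.character(subclass)
  subclass[is.na(subclass)] <- "unassigned"
  if (length(subclass) != ncol(counts))
    stop("'subclass' must have one label per cell")
  if (is.null(total)) total <- colSums(counts)
  if (length(total) != ncol(counts))
    stop("'total' must have one value per cell")
  cd <- DataFrame(subclass = subclass, total = as.numeric(total),
                  genesDetected = colSums(counts >= 1),
                  row.names = colnames(counts))
  new("CellCounts",
      SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

#' @rdname subclassLabels
#' @export
setMethod("subclassLabels", "CellCounts",
          function(x) as.character(colData(x)$subclass))

#' @rdname cellTotals
#' @export
setMethod("cellTotals", "CellCounts", function(x) colData(x)$total)

## ---------------------------------------------------------------------------
## Junction containers
## ---------------------------------------------------------------------------

#' JunctionCounts: per cell x exon-event inclusion/exclusion reads
#'
#' A [SummarizedExperiment::SummarizedExperiment] with exon events in
#' rows and cells in columns, carrying two assays: `I` (inclusion
#' junction reads) and `E` (exclusion junction reads). Row metadata
#' holds `gene`, `event` and `variantGroup`; events that are mutually
#' exclusive splice-site variants of one exon (e.g. "23a"/"23b") share a
#' `variantGroup` value and their `E` rows hold the shared exclusion
#' count. Cell metadata mirrors [CellCounts] (`subclass`, `total`).
#'
#' @export
setClass("JunctionCounts", contains = "SummarizedExperiment")

setValidity("JunctionCounts", function(object) {
  msg <- NULL
  for (a in c("I", "E"))
    if (!a %in% names(assays(object)))
      msg <- c(msg, sprintf("assay '%s' is required", a))
    else if (any(assays(object)[[a]] < 0))
      msg <- c(msg, sprintf("assay '%s' must be non-negative", a))
  for (col in c("gene", "event"))
    if (!col %in% names(rowData(object)))
      msg <- c(msg, sprintf("rowData column '%s' is required", col))
  if (is.null(msg)) TRUE else msg
})

#' Construct a JunctionCounts object
#'
#' @param I,E events x cells matrices of inclusion / exclusion junction
#'   read counts (non-negative integers, same dimensions).
#' @param gene,event character vectors describing each row.
#' @param variantGroup optional character vector; events sharing a value
#'   are treated as mutually exclusive junction variants. `NA` for
#'   ordinary cassette events.
#' @param subclass,total optional per-cell metadata (see [CellCounts]).
#' @return a [JunctionCounts] object.
#' @export
JunctionCounts <- function(I, E, gene, event, variantGroup = NULL,
                           subclass = NULL, total = NULL) {
  I <- as.matrix(I); E <- as.matrix(E)
  if (!all(dim(I) == dim(E))) stop("'I' and 'E' must have equal dimensions")
  if (length(gene) != nrow(I) || length(event) != nrow(I))
    stop("'gene' and 'event' must have one entry per row")
  if (is.null(variantGroup)) variantGroup <- rep(NA_character_, nrow(I))
  if (is.null(colnames(I)))
    colnames(I) <- colnames(E) <- paste0("cell", seq_len(ncol(I)))
  rn <- paste(gene, event, sep = ".")
  rownames(I) <- rownames(E) <- rn
  if (is.null(subclass)) subclass <- rep("unassigned", ncol(I))
  if (is.null(total)) total <- rep(NA_real_, ncol(I))
  new("JunctionCounts", SummarizedExperiment(
    assays = list(I = I, E = E),
    rowData = DataFrame(gene = as.character(gene),
                        event = as.character(event),
                        variantGroup = as.character(variantGroup),
                        row.names = rn),
    colData = DataFrame(subclass = as.character(subclass),
                        total = as.numeric(total),
                        row.names = colnames(I))))
}

#' @rdname subclassLabels
#' @export
setMethod("subclassLabels", "JunctionCounts",
          function(x) as.character(colData(x)$subclass))

#' @rdname cellTotals
#' @export
setMethod("cellTotals", "JunctionCounts", function(x) colData(x)$total)

## ---------------------------------------------------------------------------
## EIP matrix
## ---------------------------------------------------------------------------

#' EIPMatrix: exon inclusion proportions with coverage
#'
#' Holds EIP values in \eqn{[0,1]} (or `NA` where undetected) for exon
#' events (rows) against cells or subclasses (columns), the supporting
#' junction read counts, and -- at subclass level -- the number of
#' contributing cells per entry.
#'
#' @slot eip numeric matrix of inclusion proportions (`NA` = missing).
#' @slot reads numeric matrix of supporting read counts (I + E mass).
#' @slot nCells numeric matrix of contributing cells (subclass level;
#'   zero-row matrix at cell level).
#' @slot level `"cell"` or `"subclass"`.
#' @export
setClass("EIPMatrix", representation(eip = "matrix", reads = "matrix",
                                     nCells = "matrix", level = "character"))

setValidity("EIPMatrix", function(object) {
  v <- object@eip[!is.na(object@eip)]
  if (length(v) && (any(v < -1e-9) || any(v > 1 + 1e-9)))
    return("EIP values must lie in [0,1]")
  if (!object@level %in% c("cell", "subclass"))
    return("level must be 'cell' or 'subclass'")
  TRUE
})

setMethod("show", "EIPMatrix", function(object) {
  cat(sprintf("EIPMatrix (%s level): %d events x %d %ss, %.1f%% observed\n",
              object@level, nrow(object@eip), ncol(object@eip),
              object@level, 100 * mean(!is.na(object@eip))))
})

#' Extract the EIP value matrix
#' @param x an [EIPMatrix].
#' @return numeric matrix of inclusion proportions.
#' @export
eipValues <- function(x) x@eip

## ---------------------------------------------------------------------------
## 2D vessel imaging
## ---------------------------------------------------------------------------

#' VesselImage: calibrated 2D intensity image with optional ROI
#'
#' @slot pixels numeric matrix of intensities (rows = y, cols = x).
#' @slot pixelSize micrometres per pixel (scalar, isotropic).
#' @slot roi two-column matrix of polygon vertices in micrometres
#'   (x, y), or a 0-row matrix when the whole frame is the ROI.
#' @export
setClass("VesselImage", representation(pixels = "matrix",
                                       pixelSize = "numeric",
                                       roi = "matrix"))

setValidity("VesselImage", function(object) {
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar")
  if (nrow(object@roi) > 0 && ncol(object@roi) != 2)
    return("roi must be a two-column (x, y) matrix in micrometres")
  TRUE
})

#' Construct a VesselImage
#' @param pixels numeric intensity matrix.
#' @param pixelSize micrometres per pixel (> 0).
#' @param roi optional polygon vertex matrix (x, y in um).
#' @return a [VesselImage].
#' @export
VesselImage <- function(pixels, pixelSize, roi = NULL) {
  if (is.null(roi)) roi <- matrix(numeric(0), ncol = 2)
  new("VesselImage", pixels = as.matrix(pixels),
      pixelSize = as.numeric(pixelSize), roi = as.matrix(roi))
}

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "VesselImage", function(x) x@pixelSize)

setMethod("show", "VesselImage", function(object) {
  cat(sprintf("VesselImage: %d x %d px at %.3g um/px (%s ROI)\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              if (nrow(object@roi)) "polygon" else "full-frame"))
})

#' VesselMask: binary vessel segmentation
#'
#' @slot mask logical matrix, same shape as the source image.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("VesselMask", representation(mask = "matrix", pixelSize = "numeric"))

#' Construct a VesselMask
#' @param mask logical matrix.
#' @param pixelSize micrometres per pixel (> 0).
#' @return a [VesselMask].
#' @export
VesselMask <- function(mask, pixelSize) {
  m <- as.matrix(mask); storage.mode(m) <- "logical"
  new("VesselMask", mask = m, pixelSize = as.numeric(pixelSize))
}

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "VesselMask", function(x) x@pixelSize)

setMethod("show", "VesselMask", function(object) {
  cat(sprintf("VesselMask: %d x %d px, %.2f%% vessel\n",
              nrow(object@mask), ncol(object@mask), 100 * mean(object@mask)))
})

#' VesselSkeleton: one-pixel centreline with length and branch points
#'
#' @slot skeleton logical matrix (subset of the mask).
#' @slot pixelSize micrometres per pixel.
#' @slot totalLength total centreline length in micrometres (8-connected
#'   chain length, diagonal steps count sqrt(2)).
#' @slot branchPoints two-column matrix of consolidated branch-point
#'   coordinates in micrometres (x, y).
#' @export
setClass("VesselSkeleton",
         representation(skeleton = "matrix", pixelSize = "numeric",
                        totalLength = "numeric", branchPoints = "matrix"))

setMethod("show", "VesselSkeleton", function(object) {
  cat(sprintf("VesselSkeleton: length %.1f um, %d branch point(s)\n",
              object@totalLength, nrow(object@branchPoints)))
})

#' VesselMetrics: the three headline vascular readouts
#'
#' @slot vaf vessel area fraction within the ROI, percent.
#' @slot meanDiameter mean vessel diameter in micrometres (`NA` when the
#'   mask is empty).
#' @slot branchDensity branch points per 100 um of vessel (`NA` when the
#'   skeleton is empty).
#' @slot totalLength skeleton length in micrometres.
#' @slot nBranch consolidated branch-point count.
#' @export
setClass("VesselMetrics",
         representation(vaf = "numeric", meanDiameter = "numeric",
                        branchDensity = "numeric", totalLength = "numeric",
                        nBranch = "numeric"))

setMethod("show", "VesselMetrics", function(object) {
  cat(sprintf(paste0("VesselMetrics: VAF %.2f%%, mean diameter %.2f um, ",
                     "%.3g branches / 100 um (length %.1f um)\n"),
              object@vaf, object@meanDiameter, object@branchDensity,
              object@totalLength))
})

## ---------------------------------------------------------------------------
## 3D imaging
## ---------------------------------------------------------------------------

#' Volume3D: calibrated 3D intensity volume
#'
#' Voxels are indexed `[x, y, z]`; `voxelSize` gives the edge lengths in
#' micrometres along each axis (anisotropy allowed, e.g. confocal stacks
#' with coarser z steps).
#'
#' @slot voxels numeric 3D array.
#' @slot voxelSize length-3 numeric, um per voxel along (x, y, z).
#' @export
setClass("Volume3D", representation(voxels = "array", voxelSize = "numeric"))

setValidity("Volume3D", function(object) {
  if (length(dim(object@voxels)) != 3) return("voxels must be a 3D array")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be three positive values (x, y, z)")
  TRUE
})

#' Construct a Volume3D
#' @param voxels 3D numeric array indexed `[x, y, z]`.
#' @param voxelSize um per voxel along (x, y, z).
#' @return a [Volume3D].
#' @export
Volume3D <- function(voxels, voxelSize) {
  new("Volume3D", voxels = voxels, voxelSize = as.numeric(voxelSize))
}

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Volume3D", function(x) x@voxelSize)

#' SurfaceMask3D: binary 3D surface (e.g. CD31-labelled endothelium)
#'
#' @slot mask logical 3D array indexed `[x, y, z]`.
#' @slot voxelSize um per voxel along (x, y, z).
#' @export
setClass("SurfaceMask3D", representation(mask = "array",
                                         voxelSize = "numeric"))

#' Construct a SurfaceMask3D
#' @param mask logical 3D array.
#' @param voxelSize um per voxel along (x, y, z).
#' @return a [SurfaceMask3D].
#' @export
SurfaceMask3D <- function(mask, voxelSize) {
  m <- mask; storage.mode(m) <- "logical"
  new("SurfaceMask3D", mask = m, voxelSize = as.numeric(voxelSize))
}

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "SurfaceMask3D", function(x) x@voxelSize)

#' SpotSet: detected 3D puncta
#'
#' @slot centers three-column matrix of punctum centres in um (x, y, z),
#'   sub-voxel resolved.
#' @slot quality per-punctum detection quality (background-subtracted
#'   peak response).
#' @slot diameters expected x/y/z diameters (um) used for detection.
#' @export
setClass("SpotSet", representation(centers = "matrix", quality = "numeric",
                                   diameters = "numeric"))

setMethod("show", "SpotSet", function(object) {
  cat(sprintf("SpotSet: %d puncta (expected diameters %s um)\n",
              nrow(object@centers),
              paste(object@diameters, collapse = "/")))
})

#' Punctum centres in micrometres
#' @param x a [SpotSet].
#' @return three-column matrix (x, y, z) in um.
#' @export
spotCenters <- function(x) x@centers

## ---------------------------------------------------------------------------
## Fluorometry
## ---------------------------------------------------------------------------

#' StandardCurve: fitted linear fluorescence standard curve
#'
#' @slot slope fluorescence units per concentration unit.
#' @slot intercept fluorescence at zero concentration.
#' @slot r2 coefficient of determination of the fit.
#' @slot range fitted concentration range `c(min, max)`; readings that
#'   invert outside it are flagged as extrapolations.
#' @export
setClass("StandardCurve",
         representation(slope = "numeric", intercept = "numeric",
                        r2 = "numeric", range = "numeric"))

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: reading = %.4g * conc + %.4g (R2 = %.4f)\n",
              object@slope, object@intercept, object@r2))
})
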