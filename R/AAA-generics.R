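#' @import methods
NULL

#' Pixel or voxel calibration of an image-like object
#'
#' @param x an object carrying a spatial calibration.
#' @return numeric scalar (2D, um/px) or length-3 numeric (3D, um/voxel
#'   along x, y, z).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Subclass labels attached to cells
#'
#' @param x a [CellCounts] or [JunctionCounts] object.
#' @return character vector, one label per cell.
#' @export
setGeneric("subclassLabels", function(x) standardGeneric("subclassLabels"))

#' Per-cell total mapped reads
#'
#' @param x a [CellCounts] or [JunctionCounts] object.
#' @return numeric vector of totals, one per cell.
#' @export
setGeneric("cellTotals", function(x) standardGeneric("cellTotals"))
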