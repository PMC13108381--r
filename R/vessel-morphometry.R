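## 2D vascular morphometry: raw image -> preprocessing -> vesselness ->
## adaptive segmentation -> width-based cleanup -> skeleton metrics.

#' @importFrom EBImage medianFilter clahe gblur distmap bwlabel Image imageData
NULL

## strip the EBImage Image class back to a plain matrix
asMat <- function(x) {
  m <- imageData(x)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

normalize01 <- function(m) {
  r <- range(m, finite = TRUE)
  if (diff(r) <= .Machine$double.eps) return(m - r[1])
  (m - r[1]) / diff(r)
}

#' Preprocess a vessel image (median filter + CLAHE)
#'
#' Median filtering suppresses shot noise; Contrast Limited Adaptive
#' Histogram Equalization evens out illumination and boosts local
#' vessel/background contrast. The result is rescaled to \eqn{[0,1]}.
#' Constant images pass through unchanged (both operators are identity
#' on flat input).
#'
#' @param image a [VesselImage].
#' @param medianRadius median filter radius in pixels (>= 1).
#' @param claheClip CLAHE clip limit (default 3).
#' @param claheTiles number of CLAHE tiles per axis (default 8).
#' @return a [VesselImage] with intensities in \eqn{[0,1]}.
#' @export
preprocessVesselImage <- function(image, medianRadius = 2, claheClip = 3,
                                  claheTiles = 8) {
  stopifnot(is(image, "VesselImage"))
  if (medianRadius < 1) stop("median radius must be >= 1 px")
  m <- normalize01(image@pixels)
  if (diff(range(m)) <= .Machine$double.eps)
    return(VesselImage(m, image@pixelSize, roiOrNull(image)))
  m <- asMat(medianFilter(Image(m), medianRadius))
  m <- normalize01(m)
  tiles <- max(2, min(claheTiles, floor(min(dim(m)) / 8)))
  m <- asMat(clahe(Image(m), nx = tiles, ny = tiles,
                       limit = claheClip))
  VesselImage(normalize01(m), image@pixelSize, roiOrNull(image))
}

roiOrNull <- function(image) if (nrow(image@roi)) image@roi else NULL

## Hessian of a Gaussian-smoothed image by central differences.
hessian2d <- function(m) {
  pad <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    x[pmin(pmax(seq_len(nr) + dr, 1), nr),
      pmin(pmax(seq_len(nc) + dc, 1), nc), drop = FALSE]
  }
  list(rr = pad(m, 1, 0) + pad(m, -1, 0) - 2 * m,
       cc = pad(m, 0, 1) + pad(m, 0, -1) - 2 * m,
       rc = (pad(m, 1, 1) + pad(m, -1, -1) -
               pad(m, 1, -1) - pad(m, -1, 1)) / 4)
}

#' Multiscale Frangi vesselness
#'
#' Hessian-eigenvalue ridge enhancement of bright tubular structures.
#' For each scale, the image is Gaussian-smoothed at sigma = scale (in
#' um, converted to pixels), the scale-normalized Hessian eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2|} are computed, and the Frangi
#' response combines blobness suppression
#' \eqn{\exp(-R_b^2 / 2\beta^2)}, \eqn{R_b = \lambda_1/\lambda_2}, with
#' structure strength \eqn{1 - \exp(-S^2 / 2c^2)},
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}, zeroed where
#' \eqn{\lambda_2 \ge 0} (dark or flat). The per-pixel maximum over
#' scales is returned, rescaled to \eqn{[0,1]}.
#'
#' @param image a [VesselImage] (preprocessed).
#' @param scalesUm Gaussian scales in um; a good set spans half the
#'   expected vessel widths (default `c(1, 1.5, 2, 3)`).
#' @param beta blobness sensitivity (default 0.5).
#' @param cFactor structure-strength constant as a fraction of the
#'   maximum Hessian norm at each scale (default 0.5).
#' @return a [VesselImage] holding the vesselness map in \eqn{[0,1]}.
#' @export
frangiVesselness <- function(image, scalesUm = c(1, 1.5, 2, 3),
                             beta = 0.5, cFactor = 0.5) {
  stopifnot(is(image, "VesselImage"))
  if (any(scalesUm <= 0)) stop("scales must be positive")
  m <- image@pixels
  best <- matrix(0, nrow(m), ncol(m))
  for (sUm in scalesUm) {
    sig <- sUm / image@pixelSize
    sm <- asMat(gblur(Image(m), sigma = sig))
    h <- hessian2d(sm)
    hrr <- h$rr * sig^2; hcc <- h$cc * sig^2; hrc <- h$rc * sig^2
    tmp <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    mu <- (hrr + hcc) / 2
    e1 <- mu + tmp; e2 <- mu - tmp
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)   # smaller magnitude
    l2 <- ifelse(swap, e1, e2)   # larger magnitude
    S <- sqrt(l1^2 + l2^2)
    cc <- cFactor * max(S)
    if (cc <= 0) next
    Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cc^2)))
    v[l2 >= 0] <- 0
    best <- pmax(best, v)
  }
  VesselImage(normalize01(best), image@pixelSize, roiOrNull(image))
}

#' Local adaptive Gaussian threshold
#'
#' Segments bright structures by comparing each pixel against a
#' Gaussian-weighted local mean: a pixel is vessel when its value
#' exceeds the local mean by more than `offset`. Vessels must be bright
#' on dark background; on an inverted image the mask inverts
#' accordingly. A blank image yields an empty mask for any positive
#' offset.
#'
#' @param vesselness a [VesselImage] (typically the vesselness map).
#' @param blockSizePx odd window size in pixels (>= 3) controlling the
#'   Gaussian weighting extent (sigma = blockSizePx / 6).
#' @param offset strictness: larger values segment more conservatively
#'   (default 0.02).
#' @return a [VesselMask].
#' @export
segmentVessels <- function(vesselness, blockSizePx = 65, offset = 0.02) {
  stopifnot(is(vesselness, "VesselImage"))
  if (blockSizePx < 3 || blockSizePx %% 2 == 0)
    stop("block size must be an odd integer >= 3")
  m <- vesselness@pixels
  localMean <- asMat(gblur(Image(m), sigma = blockSizePx / 6))
  VesselMask(m > localMean + offset, vesselness@pixelSize)
}

#' Remove mask components thinner than a minimum width
#'
#' A connected component is removed when its maximum inscribed width
#' (twice the largest Euclidean distance-transform value inside it)
#' falls below `minWidthUm`. This is a width criterion, not an area
#' one: long thin debris is removed, genuine capillaries at or above
#' the width threshold are kept. Raising the threshold can only remove
#' pixels (monotone).
#'
#' @param mask a [VesselMask].
#' @param minWidthUm minimum inscribed width in um (default 2).
#' @return the refined [VesselMask].
#' @export
refineMask <- function(mask, minWidthUm = 2) {
  stopifnot(is(mask, "VesselMask"))
  m <- mask@mask
  if (!any(m)) return(mask)
  lab <- asMat(bwlabel(Image(m)))
  dt <- asMat(distmap(Image(m)))
  width <- tapply(dt[m], lab[m], max) * 2 * mask@pixelSize
  drop <- as.numeric(names(width)[width < minWidthUm])
  m[lab %in% drop] <- FALSE
  VesselMask(m, mask@pixelSize)
}

## --- Zhang-Suen thinning -------------------------------------------------

shiftMat <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
  out
}

thinOnce <- function(m, sub) {
  ## neighbours P2..P9 clockwise from north (row-1)
  p2 <- shiftMat(m, -1, 0); p3 <- shiftMat(m, -1, 1)
  p4 <- shiftMat(m, 0, 1);  p5 <- shiftMat(m, 1, 1)
  p6 <- shiftMat(m, 1, 0);  p7 <- shiftMat(m, 1, -1)
  p8 <- shiftMat(m, 0, -1); p9 <- shiftMat(m, -1, -1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  A <- matrix(0, nrow(m), ncol(m))
  for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
  cond <- m & B >= 2 & B <= 6 & A == 1
  if (sub == 1) cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  else          cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  m & !cond
}

#' Skeletonize a vessel mask and measure centreline length
#'
#' Zhang-Suen thinning reduces the mask to a one-pixel-wide
#' 8-connected skeleton. Total length is the chain length: each
#' orthogonally adjacent skeleton pair contributes one pixel step, each
#' diagonal pair (not short-cut by an orthogonal bridge pixel)
#' contributes sqrt(2), converted to um.
#'
#' @param mask a refined [VesselMask].
#' @return a [VesselSkeleton] (branch points not yet populated; see
#'   [findBranchPoints()]).
#' @export
skeletonizeMask <- function(mask) {
  stopifnot(is(mask, "VesselMask"))
  m <- mask@mask
  if (any(m)) repeat {
    m1 <- thinOnce(m, 1)
    m2 <- thinOnce(m1, 2)
    if (identical(m2, m)) break
    m <- m2
  }
  new("VesselSkeleton", skeleton = m, pixelSize = mask@pixelSize,
      totalLength = chainLength(m) * mask@pixelSize,
      branchPoints = matrix(numeric(0), 0, 2))
}

## 8-connected chain length in pixel units
chainLength <- function(m) {
  if (!any(m)) return(0)
  east <- m & shiftMat(m, 0, -1)   # pixel has an eastern neighbour
  south <- m & shiftMat(m, -1, 0)
  se <- m & shiftMat(m, -1, -1)
  ne <- m & shiftMat(m, 1, -1)
  ## drop diagonals bridged by an orthogonal pair
  seBridge <- (m & shiftMat(m, 0, -1) & shiftMat(se, 0, 0) &
                 shiftMat(m, -1, 0))
  seCount <- se & !(shiftMat(m, 0, -1) | shiftMat(m, -1, 0))
  neCount <- ne & !(shiftMat(m, 0, -1) | shiftMat(m, 1, 0))
  sum(east) + sum(south) + sqrt(2) * (sum(seCount) + sum(neCount))
}

neighborCount <- function(m) {
  shiftMat(m, -1, 0) + shiftMat(m, 1, 0) + shiftMat(m, 0, -1) +
    shiftMat(m, 0, 1) + shiftMat(m, -1, -1) + shiftMat(m, -1, 1) +
    shiftMat(m, 1, -1) + shiftMat(m, 1, 1)
}

#' Locate and consolidate skeleton branch points
#'
#' Raw branch pixels are skeleton pixels with at least three skeleton
#' neighbours (8-connectivity). Clusters of raw branch pixels closer
#' than `minSeparationUm` are merged to their centroid by single
#' linkage, repeatedly, until all returned points are pairwise at least
#' `minSeparationUm` apart. Points are processed in lexicographic
#' coordinate order, so the result is independent of input ordering.
#'
#' @param skeleton a [VesselSkeleton].
#' @param minSeparationUm minimum branch-point separation (default 10).
#' @return the [VesselSkeleton] with its `branchPoints` slot filled
#'   (x, y in um).
#' @export
findBranchPoints <- function(skeleton, minSeparationUm = 10) {
  stopifnot(is(skeleton, "VesselSkeleton"))
  m <- skeleton@skeleton
  raw <- which(m & neighborCount(m) >= 3, arr.ind = TRUE)
  px <- skeleton@pixelSize
  pts <- cbind(x = (raw[, "col"] - 0.5) * px,
               y = (raw[, "row"] - 0.5) * px)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  while (nrow(pts) > 1) {
    d <- stats::dist(pts)
    if (min(d) >= minSeparationUm) break
    cl <- stats::cutree(stats::hclust(d, method = "single"),
                        h = minSeparationUm)
    pts <- do.call(rbind, lapply(split(seq_len(nrow(pts)), cl),
                                 function(i) colMeans(pts[i, , drop = FALSE])))
    pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  }
  colnames(pts) <- c("x", "y")
  skeleton@branchPoints <- pts
  skeleton
}

## even-odd point-in-polygon, vectorized over points
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

roiMask <- function(dims, pixelSize, roi) {
  if (is.null(roi) || nrow(roi) == 0)
    return(matrix(TRUE, dims[1], dims[2]))
  xs <- (seq_len(dims[2]) - 0.5) * pixelSize
  ys <- (seq_len(dims[1]) - 0.5) * pixelSize
  X <- matrix(xs, dims[1], dims[2], byrow = TRUE)
  Y <- matrix(ys, dims[1], dims[2])
  matrix(pointInPolygon(as.vector(X), as.vector(Y), roi),
         dims[1], dims[2])
}

#' Vascular metrics within a region of interest
#'
#' Computes the three headline readouts: vessel area fraction
#' (VAF, percent of ROI pixels that are vessel), mean vessel diameter
#' (twice the Euclidean distance-transform value of the mask, sampled
#' on skeleton pixels, in um) and branch-point density (branch points
#' per 100 um of vessel length). The ROI polygon clips the mask before
#' VAF and the skeleton before the length/branch metrics
#' (centre-in-polygon rasterization).
#'
#' @param mask a refined [VesselMask].
#' @param skeleton a [VesselSkeleton] with branch points.
#' @param roi optional polygon (x, y in um); default whole frame.
#' @return a [VesselMetrics].
#' @export
vesselMetrics <- function(mask, skeleton, roi = NULL) {
  stopifnot(is(mask, "VesselMask"), is(skeleton, "VesselSkeleton"))
  px <- mask@pixelSize
  rm_ <- roiMask(dim(mask@mask), px, roi)
  if (!any(rm_)) stop("ROI does not intersect the image")
  vaf <- 100 * sum(mask@mask & rm_) / sum(rm_)
  skel <- skeleton@skeleton & rm_
  len <- chainLength(skel) * px
  bp <- skeleton@branchPoints
  if (nrow(bp) && !is.null(roi) && nrow(roi))
    bp <- bp[pointInPolygon(bp[, 1], bp[, 2], roi), , drop = FALSE]
  nb <- nrow(bp)
  if (len == 0 && nb > 0)
    stop("inconsistent inputs: branch points with zero vessel length")
  meanDiam <- NA_real_
  if (any(skel)) {
    dt <- asMat(distmap(Image(mask@mask)))
    meanDiam <- mean(2 * dt[skel] * px)
  }
  new("VesselMetrics", vaf = vaf, meanDiameter = meanDiam,
      branchDensity = if (len > 0) 100 * nb / len else NA_real_,
      totalLength = len, nBranch = as.numeric(nb))
}

#' Region area normalized to a reference region
#'
#' Ratio quantification of anatomical region areas, e.g. ventricle area
#' normalized to total brain-slice area.
#'
#' @param regionMask,referenceMask [VesselMask]-like binary masks
#'   sharing the same calibration.
#' @return list with `regionArea` (um^2), `referenceArea` (um^2) and
#'   `normalized` (their ratio).
#' @export
regionAreaMetrics <- function(regionMask, referenceMask) {
  stopifnot(is(regionMask, "VesselMask"), is(referenceMask, "VesselMask"))
  if (regionMask@pixelSize != referenceMask@pixelSize)
    stop("masks must share pixel calibration")
  a <- sum(regionMask@mask) * regionMask@pixelSize^2
  ref <- sum(referenceMask@mask) * referenceMask@pixelSize^2
  if (ref == 0) stop("reference area is zero")
  list(regionArea = a, referenceArea = ref, normalized = a / ref)
}

#' Full vessel morphometry pipeline
#'
#' Convenience wrapper running preprocessing, Frangi enhancement,
#' adaptive segmentation, width-based cleanup, skeletonization, branch
#' consolidation and metric extraction with the package defaults.
#'
#' Segmentation is detect-then-delineate: the adaptive threshold on the
#' vesselness map finds where vessels are (high specificity, but the
#' Frangi ridge is wider than the vessel), while the same threshold on
#' the preprocessed intensity delineates vessel boundaries accurately;
#' the final mask keeps the intensity-threshold components touched by
#' vesselness detections, so isolated bright blobs without tubular
#' support are discarded and vessel widths remain faithful.
#'
#' @param image a [VesselImage]; its ROI (if any) is used for metrics.
#' @param scalesUm Frangi scales in um.
#' @param minWidthUm minimum vessel width retained (um).
#' @param minSeparationUm branch consolidation distance (um).
#' @param medianRadius,claheClip,claheTiles see
#'   [preprocessVesselImage()].
#' @param blockSizePx,offset see [segmentVessels()] (applied to the
#'   vesselness map).
#' @param delineationOffset adaptive-threshold offset applied to the
#'   preprocessed intensity for boundary delineation (default 0.15).
#' @return list with `mask`, `skeleton` and `metrics`.
#' @export
vesselPipeline <- function(image, scalesUm = c(1, 1.5, 2, 3),
                           minWidthUm = 2, minSeparationUm = 10,
                           medianRadius = 2, claheClip = 3,
                           claheTiles = 8, blockSizePx = 65,
                           offset = 0.02, delineationOffset = 0.15) {
  pre <- preprocessVesselImage(image, medianRadius, claheClip, claheTiles)
  ves <- frangiVesselness(pre, scalesUm)
  seed <- segmentVessels(ves, blockSizePx, offset)
  outline <- segmentVessels(pre, blockSizePx, delineationOffset)
  lab <- asMat(bwlabel(Image(outline@mask)))
  keep <- setdiff(unique(lab[seed@mask & outline@mask]), 0)
  mask <- VesselMask(matrix(lab %in% keep, nrow(lab)), image@pixelSize)
  mask <- refineMask(mask, minWidthUm)
  skel <- findBranchPoints(skeletonizeMask(mask), minSeparationUm)
  roi <- roiOrNull(image)
  list(mask = mask, skeleton = skel,
       metrics = vesselMetrics(mask, skel, roi))
}
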