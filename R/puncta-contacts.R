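## 3D spot detection and proximity/coverage scoring of puncta against
## surfaces (synaptic contacts onto vessels, smFISH nucleus-proximal
## puncta, surface-surface coverage).

## --- separable Gaussian smoothing with clamped borders -------------------

gaussKernel <- function(sigma) {
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

shiftAlong <- function(arr, axis, d) {
  dims <- dim(arr)
  idx <- pmin(pmax(seq_len(dims[axis]) + d, 1), dims[axis])
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

smooth3d <- function(arr, sigmaVox) {
  for (axis in 1:3) {
    if (sigmaVox[axis] <= 0) next
    k <- gaussKernel(sigmaVox[axis])
    r <- (length(k) - 1) / 2
    out <- array(0, dim(arr))
    for (j in seq_along(k))
      out <- out + k[j] * shiftAlong(arr, axis, j - r - 1)
    arr <- out
  }
  arr
}

## --- exact anisotropic Euclidean distance transform ----------------------
## (Felzenszwalb & Huttenlocher lower-envelope algorithm, one pass per
## axis; grid spacing per axis in um)

dt1d <- function(f, s) {
  n <- length(f)
  if (all(!is.finite(f))) return(f)
  v <- integer(n); z <- numeric(n + 1)
  d <- numeric(n)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    if (!is.finite(f[q])) next
    repeat {
      p <- v[k]
      if (!is.finite(f[p])) { sepr <- -Inf }
      else sepr <- ((f[q] + (s * q)^2) - (f[p] + (s * p)^2)) /
          (2 * s * q - 2 * s * p) / s  # in index units
      if (sepr <= z[k] && k > 1L) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- sepr; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (s * (q - p))^2 + f[p]
  }
  d
}

## first pass handles all-infinite lines (empty feature set along line)
dtAxis <- function(arr, axis, spacing) {
  dims <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, dm[1], dm[2] * dm[3])
  m <- apply(m, 2, dt1d, s = spacing)
  aperm(array(m, dm), order(perm))
}

#' Anisotropic 3D Euclidean distance transform
#'
#' Exact squared-distance transform to the TRUE voxels of a 3D mask,
#' honouring per-axis voxel sizes; returns distances in um.
#'
#' @param mask logical 3D array.
#' @param voxelSize um per voxel along (x, y, z).
#' @return numeric array of distances (0 inside the mask, `Inf` when
#'   the mask is empty).
#' @export
distanceTransform3D <- function(mask, voxelSize) {
  f <- array(ifelse(mask, 0, Inf), dim(mask))
  for (axis in 1:3) f <- dtAxis(f, axis, voxelSize[axis])
  sqrt(f)
}

## --- spot detection ------------------------------------------------------

#' Detect 3D puncta by matched Gaussian smoothing
#'
#' Smooths the volume with an anisotropic Gaussian matched to the
#' expected punctum diameters (sigma = diameter / 2.355, FWHM
#' convention), estimates the background with a 3x wider Gaussian,
#' subtracts it, and returns sub-voxel local maxima whose
#' background-subtracted response reaches `qualityThreshold`. Sub-voxel
#' centres come from a per-axis quadratic fit around each maximum; ties
#' between equal maxima are broken by lexicographic voxel order.
#'
#' @param volume a [Volume3D] (single channel).
#' @param expectedDiameters x/y/z punctum diameters in um (default
#'   `c(0.6, 0.6, 1.2)`); each must be at least the voxel size on its
#'   axis.
#' @param qualityThreshold minimum background-subtracted peak response
#'   for a spot to be retained (required; the appropriate value depends
#'   on signal amplitude and noise).
#' @param backgroundFactor width of the background-estimation Gaussian
#'   relative to the detection Gaussian (default 3).
#' @return a [SpotSet].
#' @export
detectSpots <- function(volume, expectedDiameters = c(0.6, 0.6, 1.2),
                        qualityThreshold, backgroundFactor = 3) {
  stopifnot(is(volume, "Volume3D"))
  if (missing(qualityThreshold))
    stop("'qualityThreshold' is required")
  vx <- volume@voxelSize
  if (any(expectedDiameters < vx))
    stop("expected diameters must be at least one voxel on each axis")
  sig <- (expectedDiameters / 2.355) / vx
  sm <- smooth3d(volume@voxels, sig)
  bg <- smooth3d(volume@voxels, sig * backgroundFactor)
  resp <- sm - bg
  dims <- dim(resp)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  shiftPad <- function(a, axis, d) {
    dims <- dim(a)
    idx <- seq_len(dims[axis]) + d
    pad <- idx < 1 | idx > dims[axis]
    idx <- pmin(pmax(idx, 1), dims[axis])
    out <- switch(axis,
                  a[idx, , , drop = FALSE],
                  a[, idx, , drop = FALSE],
                  a[, , idx, drop = FALSE])
    if (any(pad)) switch(axis,
                         out[pad, , ] <- -Inf,
                         out[, pad, ] <- -Inf,
                         out[, , pad] <- -Inf)
    out
  }
  isMax <- array(TRUE, dims)
  for (i in seq_len(nrow(offsets))) {
    o <- as.numeric(offsets[i, ])
    s <- shiftPad(shiftPad(shiftPad(resp, 1, o[1]), 2, o[2]), 3, o[3])
    ## strict on lexicographically earlier neighbours: one spot per
    ## plateau
    first <- o[which(o != 0)[1]]
    isMax <- isMax & (if (first > 0) resp > s else resp >= s)
  }
  isMax <- isMax & resp >= qualityThreshold
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx))
    return(new("SpotSet", centers = matrix(numeric(0), 0, 3,
                                           dimnames = list(NULL, c("x", "y", "z"))),
               quality = numeric(0), diameters = expectedDiameters))
  centers <- matrix(0, nrow(idx), 3, dimnames = list(NULL, c("x", "y", "z")))
  for (p in seq_len(nrow(idx))) {
    for (axis in 1:3) {
      i <- idx[p, axis]
      delta <- 0
      if (i > 1 && i < dims[axis]) {
        lo <- idx[p, ]; hi <- idx[p, ]
        lo[axis] <- i - 1; hi[axis] <- i + 1
        f0 <- resp[matrix(idx[p, ], 1)]
        fm <- resp[matrix(lo, 1)]; fp <- resp[matrix(hi, 1)]
        den <- fm - 2 * f0 + fp
        if (den < 0) delta <- max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
      }
      centers[p, axis] <- (i - 0.5 + delta) * vx[axis]
    }
  }
  new("SpotSet", centers = centers, quality = resp[isMax],
      diameters = expectedDiameters)
}

## --- proximity and coverage ----------------------------------------------

#' Classify puncta as vessel-proximal
#'
#' A punctum is proximal when the Euclidean distance from its centre to
#' the nearest surface voxel is at most `cutoffUm`; puncta inside the
#' surface have distance zero. Distances use the anisotropy-corrected
#' distance transform sampled at the punctum's voxel.
#'
#' @param spots a [SpotSet].
#' @param surface a [SurfaceMask3D] sharing the calibration.
#' @param cutoffUm proximity cutoff in um (default 1).
#' @return list with `proximal` (logical), `distances` (um) and
#'   `count` (number of proximal puncta).
#' @export
classifyProximal <- function(spots, surface, cutoffUm = 1) {
  stopifnot(is(spots, "SpotSet"), is(surface, "SurfaceMask3D"))
  vx <- surface@voxelSize
  if (!any(surface@mask)) {
    warning("empty surface: all puncta classified non-proximal")
    d <- rep(Inf, nrow(spots@centers))
    return(list(proximal = rep(FALSE, length(d)), distances = d,
                count = 0L))
  }
  dt <- distanceTransform3D(surface@mask, vx)
  dims <- dim(surface@mask)
  ijk <- sapply(1:3, function(a)
    pmin(pmax(ceiling(spots@centers[, a] / vx[a]), 1), dims[a]))
  ijk <- matrix(ijk, ncol = 3)
  d <- dt[ijk]
  list(proximal = d <= cutoffUm, distances = d,
       count = sum(d <= cutoffUm))
}

exposedFaceAreas <- function(mask, voxelSize) {
  faceArea <- c(voxelSize[2] * voxelSize[3],   # faces normal to x
                voxelSize[1] * voxelSize[3],   # normal to y
                voxelSize[1] * voxelSize[2])   # normal to z
  per <- array(0, dim(mask))
  for (axis in 1:3) for (d in c(-1, 1)) {
    nb <- shiftAlong(mask, axis, d)
    ## border voxels: clamped shift copies the voxel itself; mark the
    ## volume boundary as exposed
    dims <- dim(mask)
    edge <- slice.index(mask, axis) == if (d == 1) dims[axis] else 1
    per <- per + faceArea[axis] * (mask & (!nb | edge))
  }
  per
}

#' Surface area of a binary 3D mask
#'
#' Counts exposed voxel faces weighted by their physical dimensions.
#' Deterministic and exact for axis-aligned shapes; for smooth curved
#' surfaces the staircase overestimates area (up to ~4/pi for a
#' cylinder's lateral surface), which cancels in coverage ratios.
#'
#' @param surface a [SurfaceMask3D].
#' @return surface area in um^2 (0 for an empty mask).
#' @examples
#' m <- array(FALSE, c(12, 12, 12)); m[2:11, 2:11, 2:11] <- TRUE
#' estimateSurfaceArea(SurfaceMask3D(m, c(1, 1, 1)))  # 600
#' @export
estimateSurfaceArea <- function(surface) {
  stopifnot(is(surface, "SurfaceMask3D"))
  if (!any(surface@mask)) return(0)
  sum(exposedFaceAreas(surface@mask, surface@voxelSize))
}

#' Puncta density per unit surface area
#'
#' @param count proximal puncta count.
#' @param area surface area in um^2 (> 0).
#' @return density per um^2.
#' @export
punctaDensity <- function(count, area) {
  if (area <= 0) stop("surface area must be > 0")
  count / area
}

#' Surface-surface coverage percentage
#'
#' Fraction of the area of `surfaceA` lying within `contactRadiusUm` of
#' `surfaceB`, as a percentage -- the endothelial-coverage readout:
#' 100 x (colocalized surface area) / (total surface area). Coverage of
#' a surface by itself is 100% at any radius, and coverage is monotone
#' non-decreasing in the contact radius.
#'
#' @param surfaceA,surfaceB [SurfaceMask3D] objects sharing calibration.
#' @param contactRadiusUm colocalization tolerance in um; defaults to
#'   one voxel diagonal.
#' @return coverage percentage in \eqn{[0, 100]}.
#' @export
surfaceCoverage <- function(surfaceA, surfaceB, contactRadiusUm = NULL) {
  stopifnot(is(surfaceA, "SurfaceMask3D"), is(surfaceB, "SurfaceMask3D"))
  if (!any(surfaceA@mask)) stop("surfaceA is empty")
  vx <- surfaceA@voxelSize
  if (is.null(contactRadiusUm)) contactRadiusUm <- sqrt(sum(vx^2))
  areas <- exposedFaceAreas(surfaceA@mask, vx)
  total <- sum(areas)
  if (!any(surfaceB@mask)) return(0)
  d <- distanceTransform3D(surfaceB@mask, vx)
  100 * sum(areas[d <= contactRadiusUm]) / total
}

#' Count puncta within reach of labelled nuclei
#'
#' Assigns each punctum to its nearest nucleus when the distance is at
#' most `cutoffUm` (a punctum belongs to at most one cell; exact ties
#' go to the lowest label). This is the smFISH readout: transcripts
#' within 5 um of a nucleus are attributed to that cell.
#'
#' @param spots a [SpotSet].
#' @param nuclei integer-labelled 3D array (0 = background) or a list
#'   of logical masks; overlapping masks are an error.
#' @param voxelSize um per voxel along (x, y, z).
#' @param cutoffUm assignment cutoff (default 5).
#' @return named integer vector of per-cell puncta counts (one entry
#'   per label, zeros included).
#' @export
nucleusProximalPuncta <- function(spots, nuclei, voxelSize, cutoffUm = 5) {
  stopifnot(is(spots, "SpotSet"))
  if (is.list(nuclei)) {
    stacked <- Reduce("+", lapply(nuclei, function(m) m * 1))
    if (any(stacked > 1)) stop("overlapping nuclei labels")
    lab <- array(0L, dim(nuclei[[1]]))
    for (i in seq_along(nuclei)) lab[nuclei[[i]]] <- i
    nuclei <- lab
  }
  labels <- sort(setdiff(unique(as.vector(nuclei)), 0))
  np <- nrow(spots@centers)
  dmat <- matrix(Inf, np, length(labels))
  dims <- dim(nuclei)
  ijk <- sapply(1:3, function(a)
    pmin(pmax(ceiling(spots@centers[, a] / voxelSize[a]), 1), dims[a]))
  ijk <- matrix(ijk, ncol = 3)
  for (j in seq_along(labels)) {
    dt <- distanceTransform3D(nuclei == labels[j], voxelSize)
    dmat[, j] <- dt[ijk]
  }
  counts <- stats::setNames(integer(length(labels)),
                            paste0("cell", labels))
  if (np) {
    nearest <- apply(dmat, 1, which.min)
    dmin <- dmat[cbind(seq_len(np), nearest)]
    assigned <- nearest[dmin <= cutoffUm]
    if (length(assigned)) {
      tab <- table(factor(assigned, levels = seq_along(labels)))
      counts[] <- as.integer(tab)
    }
  }
  counts
}

#' Normalize per-cell puncta counts to the image mean
#'
#' Each cell's count is divided by the mean count over all analyzed
#' cells in the image, so the normalized counts always average to 1.
#'
#' @param counts per-cell puncta counts (>= 1 cell).
#' @return normalized counts.
#' @examples
#' normalizePunctaCounts(c(2, 4, 6))  # 0.5 1.0 1.5
#' @export
normalizePunctaCounts <- function(counts) {
  if (!length(counts)) stop("at least one cell is required")
  m <- mean(counts)
  if (m == 0) stop("mean puncta count is zero; nothing to normalize to")
  counts / m
}
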