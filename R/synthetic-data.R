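## Synthetic-data generators. Every downstream stage (EIP estimation,
## tau, vessel morphometry, contact scoring, fluorometry) can be
## exercised against data whose ground truth is known by construction.

## One global seed governs all sub-generators: each generator draws from
## an independently derived stream so stages can be regenerated in
## isolation without disturbing each other.
deriveSeed <- function(seed, stream) {
  ((as.numeric(seed) %% 1000003) * 2011 + 7919 * stream) %% 2147483647
}

## ---------------------------------------------------------------------------
## Splicing truth and junction-read simulation
## ---------------------------------------------------------------------------

#' SplicingTruth: generative ground truth for junction-read simulation
#'
#' @slot psi events x subclasses matrix of true inclusion proportions in
#'   \eqn{[0,1]}.
#' @slot cellsPerSubclass named integer vector of cells per subclass.
#' @slot meanDepth mean junction read coverage per cell and event.
#' @slot dispersion negative-binomial dispersion of the coverage
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson coverage.
#' @slot seed integer seed.
#' @export
setClass("SplicingTruth",
         representation(psi = "matrix", cellsPerSubclass = "integer",
                        meanDepth = "numeric", dispersion = "numeric",
                        seed = "numeric"))

setValidity("SplicingTruth", function(object) {
  msg <- NULL
  if (any(!is.finite(object@psi)) || any(object@psi < 0) ||
      any(object@psi > 1))
    msg <- c(msg, "psi must be finite and in [0,1]")
  if (any(object@cellsPerSubclass < 1))
    msg <- c(msg, "cells per subclass must be >= 1")
  if (object@meanDepth <= 0) msg <- c(msg, "mean depth must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SplicingTruth
#'
#' @param psi events x subclasses matrix (or vector, recycled to one
#'   event per entry) of true inclusion proportions.
#' @param cellsPerSubclass cells per subclass (named, or named by the
#'   psi columns).
#' @param meanDepth mean junction coverage per cell/event (default 50,
#'   a typical Smart-seq depth for a well-covered junction).
#' @param dispersion NB coverage dispersion (default 0.3).
#' @param seed integer seed.
#' @return a [SplicingTruth].
#' @export
SplicingTruth <- function(psi, cellsPerSubclass, meanDepth = 50,
                          dispersion = 0.3, seed = 1) {
  if (is.null(dim(psi)))
    psi <- matrix(psi, nrow = 1,
                  dimnames = list("event1", names(psi)))
  if (is.null(colnames(psi)))
    colnames(psi) <- paste0("sub", seq_len(ncol(psi)))
  if (is.null(rownames(psi)))
    rownames(psi) <- paste0("event", seq_len(nrow(psi)))
  if (length(cellsPerSubclass) == 1)
    cellsPerSubclass <- rep(cellsPerSubclass, ncol(psi))
  if (is.null(names(cellsPerSubclass)))
    names(cellsPerSubclass) <- colnames(psi)
  new("SplicingTruth", psi = psi,
      cellsPerSubclass = as.integer(cellsPerSubclass),
      meanDepth = meanDepth, dispersion = dispersion, seed = seed)
}

rcoverage <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate per-cell junction reads from a splicing ground truth
#'
#' For each cell and exon event, draws a coverage N from a
#' negative-binomial distribution and classifies each of the N junction
#' reads as an inclusion read with probability 2 psi / (1 + psi),
#' otherwise an exclusion read. An including transcript carries two
#' inclusion junctions while a skipping transcript carries one exclusion
#' junction, which is exactly why the EIP denominator doubles E; under
#' this read model the EIP estimator I / (I + 2E) is unbiased for psi
#' by construction.
#'
#' A matching gene-count matrix is simulated alongside (one gene per
#' event plus housekeeping genes) so that CPM-based detection gates are
#' exercised downstream; its per-cell totals are attached to the
#' junction table.
#'
#' @param truth a [SplicingTruth] object.
#' @return list with `junctions` (a [JunctionCounts]), `counts` (a
#'   [CellCounts]) and `truth` (the input, for recovery tests).
#' @export
simulateJunctionReads <- function(truth) {
  stopifnot(is(truth, "SplicingTruth"))
  validObject(truth)
  set.seed(deriveSeed(truth@seed, 1))
  psi <- truth@psi
  cps <- truth@cellsPerSubclass
  labels <- rep(colnames(psi), cps)
  ncell <- length(labels)
  nev <- nrow(psi)
  I <- E <- matrix(0L, nev, ncell)
  for (s in seq_len(ncol(psi))) {
    cols <- which(labels == colnames(psi)[s])
    for (ev in seq_len(nev)) {
      p <- 2 * psi[ev, s] / (1 + psi[ev, s])
      N <- rcoverage(length(cols), truth@meanDepth, truth@dispersion)
      inc <- stats::rbinom(length(cols), N, p)
      I[ev, cols] <- inc
      E[ev, cols] <- N - inc
    }
  }
  ## companion expression matrix: one moderately expressed gene per
  ## event plus housekeeping background, so library totals are realistic
  genes <- paste0("gene", seq_len(nev))
  means <- matrix(6, nev + 20, ncol(psi),
                  dimnames = list(c(genes, paste0("hk", 1:20)),
                                  colnames(psi)))
  cc <- simulateExpressionMatrix(means, dispersion = 0.2,
                                 cellsPerSubclass = cps,
                                 seed = deriveSeed(truth@seed, 2))
  jc <- JunctionCounts(I, E, gene = genes, event = rownames(psi),
                       subclass = labels, total = cellTotals(cc))
  colnames(jc) <- colnames(cc)
  metadata(jc)$psi <- psi
  list(junctions = jc, counts = cc, truth = truth)
}

## ---------------------------------------------------------------------------
## Expression matrix simulation
## ---------------------------------------------------------------------------

## Calibrate the count-scale mean so that the expected per-cell
## log2(CPM+1) hits the requested target despite the concavity of the
## log transform (second-order delta correction, iterated).
calibrateCPM <- function(target, dispersion, scale) {
  cpm <- 2^target - 1
  for (it in 1:4) {
    mu <- cpm / scale                      # count-scale mean
    v <- (mu + dispersion * mu^2) * scale^2  # CPM-scale variance
    g <- log2(cpm + 1)
    g2 <- -1 / ((cpm + 1)^2 * log(2))      # d2/dcpm2 log2(cpm+1)
    bias <- g + g2 * v / 2 - target
    g1 <- 1 / ((cpm + 1) * log(2))
    cpm <- pmax(cpm - bias / g1, 0)
  }
  cpm
}

#' Simulate a gene-count matrix with subclass-specific expression
#'
#' Draws negative-binomial counts whose per-subclass mean log2(CPM+1)
#' recovers the specified profile within sampling error (the
#' count-scale means are delta-calibrated against the concavity of the
#' log transform). Library sizes vary log-normally across cells.
#'
#' @param means genes x subclasses matrix of target mean log2(CPM+1)
#'   values (non-negative).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts; negative values are an error.
#' @param cellsPerSubclass cells per subclass (single value recycled).
#' @param librarySize median library size (default 5e5 reads, Smart-seq
#'   scale).
#' @param libraryCV coefficient of variation of library sizes
#'   (default 0.2).
#' @param seed integer seed.
#' @return a [CellCounts] with subclass labels.
#' @export
simulateExpressionMatrix <- function(means, dispersion = 0.1,
                                     cellsPerSubclass, librarySize = 5e5,
                                     libraryCV = 0.2, seed = 1) {
  means <- as.matrix(means)
  if (any(means < 0)) stop("mean log2(CPM+1) values must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  set.seed(deriveSeed(seed, 3))
  if (is.null(colnames(means)))
    colnames(means) <- paste0("sub", seq_len(ncol(means)))
  if (is.null(rownames(means)))
    rownames(means) <- paste0("gene", seq_len(nrow(means)))
  if (length(cellsPerSubclass) == 1)
    cellsPerSubclass <- rep(cellsPerSubclass, ncol(means))
  labels <- rep(colnames(means), cellsPerSubclass)
  ncell <- length(labels)
  sdlog <- sqrt(log(1 + libraryCV^2))
  lib <- stats::rlnorm(ncell, log(librarySize) - sdlog^2 / 2, sdlog)
  scale <- 1e6 / mean(lib)
  counts <- matrix(0L, nrow(means), ncell,
                   dimnames = list(rownames(means),
                                   paste0("cell", seq_len(ncell))))
  for (s in seq_len(ncol(means))) {
    cols <- which(labels == colnames(means)[s])
    cpm <- calibrateCPM(means[, s], dispersion, scale)
    mu <- outer(cpm, lib[cols] / 1e6)
    n <- length(mu)
    counts[, cols] <- if (dispersion == 0) stats::rpois(n, mu)
                      else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  ## the matrix holds only the genes of interest; the library size plays
  ## the role of total mapped reads (the CPM denominator), exactly as an
  ## aligner-reported total would
  CellCounts(counts, subclass = labels, total = round(lib))
}

## ---------------------------------------------------------------------------
## Vessel image rendering
## ---------------------------------------------------------------------------

#' VesselGroundTruth: geometric ground truth for 2D vessel rendering
#'
#' @slot segments data.frame with columns `x0, y0, x1, y1` (endpoint
#'   coordinates, um) and `width` (um).
#' @slot imageSize image extent in um, `c(width, height)`.
#' @slot pixelSize um per pixel.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot backgroundAmp amplitude of a low-frequency background gradient.
#' @slot seed integer seed.
#' @export
setClass("VesselGroundTruth",
         representation(segments = "data.frame", imageSize = "numeric",
                        pixelSize = "numeric", noiseSd = "numeric",
                        backgroundAmp = "numeric", seed = "numeric"))

setValidity("VesselGroundTruth", function(object) {
  msg <- NULL
  s <- object@segments
  if (nrow(s)) {
    if (any(s$width <= 0)) msg <- c(msg, "segment widths must be > 0")
    xy <- c(s$x0, s$x1, s$y0, s$y1)
    lim <- rep(object@imageSize, each = 2 * nrow(s))
    if (any(c(s$x0, s$x1) < 0 | c(s$x0, s$x1) > object@imageSize[1]) ||
        any(c(s$y0, s$y1) < 0 | c(s$y0, s$y1) > object@imageSize[2]))
      msg <- c(msg, "segments must lie inside the image bounds")
  }
  if (object@pixelSize <= 0) msg <- c(msg, "pixel size must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a VesselGroundTruth
#'
#' @param segments data.frame (`x0, y0, x1, y1, width`, all um).
#' @param imageSize `c(width, height)` in um.
#' @param pixelSize um per pixel (default 0.5, a typical 20x confocal
#'   sampling).
#' @param noiseSd additive Gaussian noise SD on the unit-intensity
#'   image (default 0 = noiseless).
#' @param backgroundAmp low-frequency background amplitude (default 0).
#' @param seed integer seed.
#' @return a [VesselGroundTruth].
#' @export
VesselGroundTruth <- function(segments, imageSize, pixelSize = 0.5,
                              noiseSd = 0, backgroundAmp = 0, seed = 1) {
  segments <- as.data.frame(segments)
  new("VesselGroundTruth", segments = segments,
      imageSize = as.numeric(imageSize), pixelSize = pixelSize,
      noiseSd = noiseSd, backgroundAmp = backgroundAmp, seed = seed)
}

## signed distance (um) from pixel centres to the tube boundary of one
## segment; negative inside
segmentDistance <- function(px, py, seg) {
  dx <- seg$x1 - seg$x0; dy <- seg$y1 - seg$y0
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else
    pmin(1, pmax(0, ((px - seg$x0) * dx + (py - seg$y0) * dy) / len2))
  sqrt((px - (seg$x0 + t * dx))^2 + (py - (seg$y0 + t * dy))^2) -
    seg$width / 2
}

#' Render a vessel network image from geometric ground truth
#'
#' Draws anti-aliased tubes (one-pixel edge ramp) on a dark background,
#' optionally adds a low-frequency background gradient and additive
#' Gaussian noise, and returns the noiseless binary truth mask together
#' with the analytically derived truth metrics.
#'
#' @param truth a [VesselGroundTruth].
#' @return list with `image` (a [VesselImage]), `mask` (the noiseless
#'   truth [VesselMask]) and `truth` (list: `totalLength` um,
#'   `meanWidth` um length-weighted, `branchPoints` matrix of junction
#'   coordinates where >= 3 segment endpoints meet, `areaFraction`
#'   truth-mask fraction of the frame, percent).
#' @export
renderVesselImage <- function(truth) {
  stopifnot(is(truth, "VesselGroundTruth"))
  validObject(truth)
  set.seed(deriveSeed(truth@seed, 4))
  px <- truth@pixelSize
  nx <- round(truth@imageSize[1] / px)
  ny <- round(truth@imageSize[2] / px)
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  d <- matrix(Inf, ny, nx)
  segs <- truth@segments
  for (i in seq_len(nrow(segs)))
    d <- pmin(d, segmentDistance(X, Y, segs[i, ]))
  mask <- d <= 0
  base <- pmin(pmax(0.5 - d / px, 0), 1)   # 1-px anti-aliased edge
  img <- base
  if (truth@backgroundAmp > 0)
    img <- img + truth@backgroundAmp * (X + Y) / (max(xs) + max(ys))
  if (truth@noiseSd > 0)
    img <- img + matrix(stats::rnorm(nx * ny, 0, truth@noiseSd), ny, nx)
  ## branch points: coordinates where >= 3 segment endpoints coincide
  bp <- matrix(numeric(0), 0, 2)
  if (nrow(segs)) {
    ends <- rbind(cbind(segs$x0, segs$y0), cbind(segs$x1, segs$y1))
    key <- paste(round(ends[, 1], 6), round(ends[, 2], 6))
    tab <- table(key)
    hubs <- names(tab)[tab >= 3]
    if (length(hubs))
      bp <- ends[match(hubs, key), , drop = FALSE]
  }
  segLen <- if (nrow(segs))
    sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2) else numeric(0)
  list(image = VesselImage(img, px),
       mask = VesselMask(mask, px),
       truth = list(totalLength = sum(segLen),
                    meanWidth = if (length(segLen) && sum(segLen) > 0)
                      sum(segs$width * segLen) / sum(segLen) else NA_real_,
                    branchPoints = bp,
                    areaFraction = 100 * mean(mask)))
}

## ---------------------------------------------------------------------------
## 3D contact volume rendering
## ---------------------------------------------------------------------------

#' ContactVolumeTruth: ground truth for 3D puncta-on-vessel volumes
#'
#' The vessel is a straight cylinder along the x axis through the
#' volume centre. Puncta are placed at specified distances from the
#' cylinder surface (positive = outside, negative = inside), spread
#' along the tube at distinct azimuthal angles.
#'
#' @slot dims volume dimensions in voxels `c(nx, ny, nz)`.
#' @slot voxelSize um per voxel along (x, y, z).
#' @slot tubeRadius cylinder radius, um.
#' @slot distances per-punctum signed distance to the tube surface, um.
#' @slot amplitudes per-punctum peak intensity.
#' @slot seed integer seed.
#' @export
setClass("ContactVolumeTruth",
         representation(dims = "integer", voxelSize = "numeric",
                        tubeRadius = "numeric", distances = "numeric",
                        amplitudes = "numeric", seed = "numeric"))

setValidity("ContactVolumeTruth", function(object) {
  msg <- NULL
  if (any(object@voxelSize <= 0)) msg <- c(msg, "voxel sizes must be > 0")
  if (object@tubeRadius <= 0) msg <- c(msg, "tube radius must be > 0")
  if (any(object@distances < -object@tubeRadius))
    msg <- c(msg, "puncta cannot lie beyond the tube axis")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ContactVolumeTruth
#'
#' @param distances signed punctum-to-surface distances, um.
#' @param tubeRadius cylinder radius, um (default 4).
#' @param dims volume size in voxels `c(nx, ny, nz)` (default
#'   `c(96, 64, 48)`).
#' @param voxelSize um per voxel (default `c(0.25, 0.25, 0.5)`, a
#'   confocal-like anisotropy).
#' @param amplitudes per-punctum peak intensity (default 1).
#' @param seed integer seed.
#' @return a [ContactVolumeTruth].
#' @export
ContactVolumeTruth <- function(distances, tubeRadius = 4,
                               dims = c(96L, 64L, 48L),
                               voxelSize = c(0.25, 0.25, 0.5),
                               amplitudes = 1, seed = 1) {
  if (length(amplitudes) == 1)
    amplitudes <- rep(amplitudes, length(distances))
  new("ContactVolumeTruth", dims = as.integer(dims),
      voxelSize = as.numeric(voxelSize), tubeRadius = tubeRadius,
      distances = as.numeric(distances),
      amplitudes = as.numeric(amplitudes), seed = seed)
}

#' Render a two-channel 3D contact volume
#'
#' Channel 1 is the vessel tube (surface marker, e.g. CD31); channel 2
#' holds Gaussian puncta at the specified surface distances. Anisotropic
#' voxel sizes are honoured throughout.
#'
#' @param truth a [ContactVolumeTruth].
#' @param spotDiameters expected x/y/z puncta diameters, um (default
#'   `c(0.6, 0.6, 1.2)`); the rendered Gaussian sigma is diameter /
#'   2.355 (FWHM convention).
#' @param noiseSd additive Gaussian noise on the puncta channel.
#' @return list with `tube` ([Volume3D]), `spots` ([Volume3D]),
#'   `surface` ([SurfaceMask3D] of the tube) and `truth` (list:
#'   `centers` um, `distances` signed um, `surfaceDistance` the
#'   geometric distance used for proximity, 0 inside the tube).
#' @export
renderContactVolume <- function(truth, spotDiameters = c(0.6, 0.6, 1.2),
                                noiseSd = 0) {
  stopifnot(is(truth, "ContactVolumeTruth"))
  validObject(truth)
  set.seed(deriveSeed(truth@seed, 5))
  vx <- truth@voxelSize
  dims <- truth@dims
  ext <- dims * vx
  yc <- ext[2] / 2; zc <- ext[3] / 2
  np <- length(truth@distances)
  ## centres: spread along x, alternate azimuth so puncta stay separated
  xs <- ext[1] * (seq_len(np) + 0.5) / (np + 2)
  ang <- (seq_len(np) - 1) * 2 * pi / max(np, 1) + pi / 7
  radial <- truth@tubeRadius + truth@distances
  centers <- cbind(x = xs, y = yc + radial * cos(ang),
                   z = zc + radial * sin(ang))
  if (any(centers < 0) || any(t(centers) > ext))
    stop("punctum centre lies outside the volume")
  cx <- (seq_len(dims[1]) - 0.5) * vx[1]
  cy <- (seq_len(dims[2]) - 0.5) * vx[2]
  cz <- (seq_len(dims[3]) - 0.5) * vx[3]
  ry <- outer(cy - yc, cz - zc, function(a, b) sqrt(a^2 + b^2))
  tubeSlice <- ry <= truth@tubeRadius
  tube <- array(0, dims)
  for (i in seq_len(dims[1])) tube[i, , ] <- tubeSlice
  spots <- array(0, dims)
  sig <- spotDiameters / 2.355
  for (p in seq_len(np)) {
    gx <- exp(-(cx - centers[p, 1])^2 / (2 * sig[1]^2))
    gy <- exp(-(cy - centers[p, 2])^2 / (2 * sig[2]^2))
    gz <- exp(-(cz - centers[p, 3])^2 / (2 * sig[3]^2))
    spots <- spots + truth@amplitudes[p] *
      (outer(outer(gx, gy), gz))
  }
  if (noiseSd > 0)
    spots <- spots + array(stats::rnorm(prod(dims), 0, noiseSd), dims)
  list(tube = Volume3D(tube, vx), spots = Volume3D(spots, vx),
       surface = SurfaceMask3D(tube > 0.5, vx),
       truth = list(centers = centers, distances = truth@distances,
                    surfaceDistance = pmax(truth@distances, 0)))
}

## ---------------------------------------------------------------------------
## Standard-curve data
## ---------------------------------------------------------------------------

#' Simulate plate-reader standard-curve readings
#'
#' @param slope,intercept true line parameters (fluorescence per
#'   concentration unit; fluorescence offset).
#' @param concentrations positive concentrations of the standards.
#' @param noiseSd additive Gaussian reading noise (default 0).
#' @param seed integer seed.
#' @return data.frame with columns `concentration` and `reading`.
#' @export
generateStandardCurveData <- function(slope, intercept, concentrations,
                                      noiseSd = 0, seed = 1) {
  if (!length(concentrations)) stop("concentration list must be non-empty")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  set.seed(deriveSeed(seed, 6))
  data.frame(concentration = concentrations,
             reading = slope * concentrations + intercept +
               stats::rnorm(length(concentrations), 0, noiseSd))
}
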