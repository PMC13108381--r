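test_that("preprocessing is identity on constants and removes salt noise", {
  const <- VesselImage(matrix(0.4, 64, 64), 1)
  out <- preprocessVesselImage(const)
  expect_true(diff(range(out@pixels)) <= .Machine$double.eps)
  salt <- matrix(0, 64, 64); salt[32, 32] <- 1
  med <- preprocessVesselImage(VesselImage(salt, 1), medianRadius = 1,
                               claheTiles = 2)
  expect_equal(max(med@pixels), 0)
  expect_error(preprocessVesselImage(const, medianRadius = 0), ">= 1")
})

test_that("preprocessing increases tube contrast on a gradient background", {
  ## a dim tube on a dominant illumination gradient: adaptive
  ## equalization should recover tube/background contrast that global
  ## normalization compresses away
  r <- renderVesselImage(tubeTruth(backgroundAmp = 5, seed = 2))
  truth <- renderVesselImage(tubeTruth())$mask@mask
  michelson <- function(m) {
    a <- mean(m[truth]); b <- mean(m[!truth])
    (a - b) / (a + b)
  }
  pre <- preprocessVesselImage(r$image)
  raw <- r$image@pixels
  raw <- (raw - min(raw)) / diff(range(raw))
  expect_gt(michelson(pre@pixels), michelson(raw))
})

test_that("Frangi response is ridge selective", {
  r <- renderVesselImage(tubeTruth(width = 4, length = 100))
  v <- frangiVesselness(preprocessVesselImage(r$image))
  center <- v@pixels[200, 150:250]          # centreline row
  bg <- v@pixels[40:80, 40:80]              # far background
  expect_gt(mean(center), 10 * (mean(bg) + 1e-6))
  blank <- frangiVesselness(VesselImage(matrix(0, 64, 64), 0.5))
  expect_lt(max(blank@pixels), 1e-6)
  expect_error(frangiVesselness(v, scalesUm = c(1, -1)), "positive")
})

test_that("Frangi suppresses isotropic blobs relative to ridges", {
  ## blob and ridge of identical contrast in one image: the ridge
  ## response dominates the blob response
  px <- 0.5
  xs <- (1:200 - 0.5) * px
  X <- matrix(xs, 200, 200, byrow = TRUE); Y <- matrix(xs, 200, 200)
  blob <- exp(-((X - 30)^2 + (Y - 30)^2) / (2 * 2^2))
  tube <- exp(-((Y - 70)^2) / (2 * 2^2)) * (abs(X - 50) < 40)
  v <- frangiVesselness(VesselImage(blob + tube, px), scalesUm = 2)
  blobResp <- max(v@pixels[55:65, 55:65])
  tubeResp <- max(v@pixels[135:145, ])
  expect_lt(blobResp, 0.5 * tubeResp)
})

test_that("adaptive threshold follows the documented conventions", {
  blank <- VesselImage(matrix(0, 64, 64), 0.5)
  expect_false(any(segmentVessels(blank, 33, 0.05)@mask))
  expect_error(segmentVessels(blank, 32), "odd")
  r <- renderVesselImage(tubeTruth())
  truth <- r$mask@mask
  seg <- segmentVessels(preprocessVesselImage(r$image), 65, 0.15)
  expect_gt(sum(seg@mask & truth) / sum(truth), 0.95)
})

test_that("width refinement removes exactly the thin components", {
  px <- 0.5
  m <- matrix(FALSE, 100, 100)
  m[50, 50] <- TRUE                      # 1-px speck, width 1 um
  m[10:17, 20:80] <- TRUE                # 4 um wide bar
  m[80, 10:90] <- TRUE                   # 0.5 um wide line
  ref <- refineMask(VesselMask(m, px), minWidthUm = 2)
  expect_false(ref@mask[50, 50])
  expect_false(any(ref@mask[80, ]))
  expect_true(all(ref@mask[10:17, 20:80]))
  ## monotone: raising the threshold never adds pixels
  r2 <- refineMask(VesselMask(m, px), minWidthUm = 1)
  r3 <- refineMask(VesselMask(m, px), minWidthUm = 3)
  expect_true(all(!r3@mask | r2@mask))
})

test_that("skeleton length tracks chain geometry", {
  m <- matrix(FALSE, 50, 120)
  m[20:27, 11:110] <- TRUE              # 100 px long bar
  sk <- skeletonizeMask(VesselMask(m, 1))
  expect_true(sk@totalLength >= 90 && sk@totalLength <= 101)
  expect_equal(skeletonizeMask(VesselMask(matrix(FALSE, 10, 10),
                                          1))@totalLength, 0)
  ## L-shape: arms 60 and 41 px wide 6; thinning erodes each free tip
  ## by about half the limb width, so expect arm-sum minus tip erosion
  L <- matrix(FALSE, 90, 90)
  L[20:25, 11:70] <- TRUE
  L[20:60, 65:70] <- TRUE
  skL <- skeletonizeMask(VesselMask(L, 1))
  expect_gt(skL@totalLength, 83)
  expect_lt(skL@totalLength, 101)
})

test_that("branch points are detected and consolidated", {
  r <- renderVesselImage(yNetworkTruth())
  pl <- vesselPipeline(r$image)
  expect_equal(nrow(pl$skeleton@branchPoints), 1)
  ## straight line has no branch point
  line <- vesselPipeline(renderVesselImage(tubeTruth())$image)
  expect_equal(nrow(line$skeleton@branchPoints), 0)
  ## two junctions 5 um apart merge into one consolidated point
  segs <- data.frame(
    x0 = c(20, 100, 100, 105, 105), y0 = c(100, 100, 100, 100, 100),
    x1 = c(100, 105, 170, 170, 170), y1 = c(100, 100, 40, 100, 160),
    width = 4)
  r2 <- renderVesselImage(VesselGroundTruth(segs, c(200, 200), 0.5))
  sk <- findBranchPoints(skeletonizeMask(r2$mask), minSeparationUm = 10)
  expect_equal(nrow(sk@branchPoints), 1)
  ## pairwise separation invariant
  if (nrow(sk@branchPoints) > 1)
    expect_gte(min(dist(sk@branchPoints)), 10)
})

test_that("vessel metrics match analytic geometry of a rendered tube", {
  r <- renderVesselImage(tubeTruth(width = 4, length = 100, frame = 200))
  pl <- vesselPipeline(r$image)
  m <- pl$metrics
  expect_lt(abs(m@vaf - r$truth$areaFraction) / r$truth$areaFraction,
            0.10)
  expect_lt(abs(m@meanDiameter - 4), 0.5)
  expect_equal(m@nBranch, 0)
  expect_equal(m@branchDensity, 0)
})

test_that("empty masks yield zero VAF with undefined flags", {
  empty <- VesselMask(matrix(FALSE, 40, 40), 0.5)
  sk <- skeletonizeMask(empty)
  m <- vesselMetrics(empty, sk)
  expect_equal(m@vaf, 0)
  expect_true(is.na(m@meanDiameter))
  expect_true(is.na(m@branchDensity))
})

test_that("metrics are invariant to translation and rotation", {
  base <- tubeTruth(width = 4, length = 80)
  shifted <- VesselGroundTruth(
    data.frame(x0 = 70, y0 = 120, x1 = 150, y1 = 120, width = 4),
    imageSize = c(200, 200), pixelSize = 0.5)
  rotated <- VesselGroundTruth(                       # 90 degrees
    data.frame(x0 = 100, y0 = 60, x1 = 100, y1 = 140, width = 4),
    imageSize = c(200, 200), pixelSize = 0.5)
  res <- lapply(list(base, shifted, rotated), function(tr)
    vesselPipeline(renderVesselImage(tr)$image)$metrics)
  vafs <- vapply(res, function(m) m@vaf, numeric(1))
  diams <- vapply(res, function(m) m@meanDiameter, numeric(1))
  expect_lt(diff(range(vafs)) / mean(vafs), 0.05)
  expect_lt(diff(range(diams)), 0.25)
})

test_that("ROI clipping restricts all metrics to the polygon", {
  r <- renderVesselImage(tubeTruth(width = 4, length = 100, frame = 200))
  roi <- cbind(c(50, 150, 150, 50), c(50, 50, 150, 150))  # 100x100 um
  img <- VesselImage(r$image@pixels, 0.5, roi)
  pl <- vesselPipeline(img)
  ## tube spans the ROI: 100 um x 4 um in 10000 um^2 -> ~4%
  expect_lt(abs(pl$metrics@vaf - 4) / 4, 0.12)
  expect_error(vesselMetrics(pl$mask, pl$skeleton,
                             cbind(c(-10, -5, -5), c(-10, -5, -10))),
               "ROI")
})

test_that("region areas normalize against a reference", {
  px <- 0.5
  ref <- VesselMask(matrix(TRUE, 200, 200), px)          # 10000 um^2
  reg <- matrix(FALSE, 200, 200); reg[1:40, 1:25] <- TRUE  # 250 um^2
  out <- regionAreaMetrics(VesselMask(reg, px), ref)
  expect_equal(out$normalized, 0.025)
  expect_equal(regionAreaMetrics(ref, ref)$normalized, 1)
  half <- VesselMask(matrix(rep(c(TRUE, FALSE), each = 100), 200, 200),
                     px)
  expect_equal(regionAreaMetrics(half, ref)$normalized, 0.5)
  none <- VesselMask(matrix(FALSE, 200, 200), px)
  expect_error(regionAreaMetrics(ref, none), "zero")
})
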