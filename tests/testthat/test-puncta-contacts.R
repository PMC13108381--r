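test_that("anisotropic distance transform matches brute force", {
  set.seed(5)
  for (i in 1:5) {
    mask <- array(runif(8 * 7 * 6) < 0.15, c(8, 7, 6))
    if (!any(mask)) mask[3, 3, 3] <- TRUE
    vx <- c(0.3, 0.4, 0.8)
    expect_equal(distanceTransform3D(mask, vx), bruteDT3(mask, vx),
                 tolerance = 1e-10)
  }
})

test_that("spot detection recovers rendered puncta with sub-voxel accuracy", {
  tr <- ContactVolumeTruth(distances = 2.5, dims = c(48L, 48L, 32L),
                           seed = 6)
  vol <- renderContactVolume(tr)
  spots <- detectSpots(vol$spots, qualityThreshold = 0.2)
  expect_equal(nrow(spotCenters(spots)), 1)
  expect_lt(sqrt(sum((spotCenters(spots) - vol$truth$centers)^2)),
            max(tr@voxelSize))
  blank <- Volume3D(array(0, c(32, 32, 16)), c(0.25, 0.25, 0.5))
  expect_equal(nrow(spotCenters(detectSpots(blank,
                                            qualityThreshold = 0.1))), 0)
  expect_error(detectSpots(blank, expectedDiameters = c(0.1, 0.6, 1.2),
                           qualityThreshold = 0.1), "voxel")
})

test_that("well-separated puncta are each detected exactly once", {
  tr <- ContactVolumeTruth(distances = rep(c(0.5, 2), 5), seed = 7)
  vol <- renderContactVolume(tr, noiseSd = 0.02)
  spots <- detectSpots(vol$spots, qualityThreshold = 0.2)
  expect_equal(nrow(spotCenters(spots)), 10)
  d <- as.matrix(dist(rbind(vol$truth$centers, spotCenters(spots))))
  match_err <- apply(d[1:10, 11:20, drop = FALSE], 1, min)
  expect_lt(max(match_err), max(tr@voxelSize))
})

test_that("proximity classification reproduces constructed distances", {
  tr <- ContactVolumeTruth(distances = rep(c(0.3, 2.5), 5), seed = 8)
  vol <- renderContactVolume(tr)
  spots <- detectSpots(vol$spots, qualityThreshold = 0.2)
  cl <- classifyProximal(spots, vol$surface, cutoffUm = 1)
  expect_equal(cl$count, 5)
  ## order spots along x to align with truth ordering
  ord <- order(spotCenters(spots)[, 1])
  expect_equal(cl$proximal[ord], rep(c(TRUE, FALSE), 5))
  emptyS <- SurfaceMask3D(array(FALSE, dim(vol$surface@mask)),
                          vol$surface@voxelSize)
  expect_warning(cl0 <- classifyProximal(spots, emptyS), "empty")
  expect_equal(cl0$count, 0L)
})

test_that("puncta inside the surface have distance zero", {
  tr <- ContactVolumeTruth(distances = c(-1, 3), seed = 9)
  vol <- renderContactVolume(tr)
  spots <- detectSpots(vol$spots, qualityThreshold = 0.2)
  cl <- classifyProximal(spots, vol$surface)
  ord <- order(spotCenters(spots)[, 1])
  expect_equal(cl$distances[ord][1], 0)
})

test_that("surface area counts exposed faces exactly on boxes", {
  m <- array(FALSE, c(12, 12, 12)); m[2:11, 2:11, 2:11] <- TRUE
  expect_equal(estimateSurfaceArea(SurfaceMask3D(m, c(1, 1, 1))), 600)
  expect_equal(estimateSurfaceArea(
    SurfaceMask3D(array(FALSE, c(4, 4, 4)), c(1, 1, 1))), 0)
  ## anisotropic single voxel: 2(dy dz + dx dz + dx dy)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(estimateSurfaceArea(SurfaceMask3D(one, c(1, 2, 3))),
               2 * (2 * 3 + 1 * 3 + 1 * 2))
})

test_that("cylinder face counting matches its staircase expectation", {
  ## lateral staircase area of a voxelized cylinder is ~8 r L (the
  ## Manhattan perimeter of a circle), a documented ~4/pi upward bias
  ## relative to the smooth 2 pi r L
  tr <- ContactVolumeTruth(distances = 2, tubeRadius = 3,
                           dims = c(80L, 64L, 64L),
                           voxelSize = c(0.25, 0.25, 0.25))
  vol <- renderContactVolume(tr)
  L <- 80 * 0.25; r <- 3
  lateral <- 8 * r * L
  caps <- 2 * pi * r^2
  area <- estimateSurfaceArea(vol$surface)
  expect_lt(abs(area - (lateral + 2 * caps)) / (lateral + 2 * caps),
            0.15)
})

test_that("puncta density is simple arithmetic with guards", {
  expect_equal(punctaDensity(6, 600), 0.01)
  expect_equal(punctaDensity(0, 600), 0)
  expect_equal(punctaDensity(6, 1200), punctaDensity(6, 600) / 2)
  expect_error(punctaDensity(1, 0), "> 0")
})

test_that("surface coverage identities and monotonicity hold", {
  tr <- ContactVolumeTruth(distances = 2, tubeRadius = 3,
                           dims = c(48L, 48L, 32L))
  vol <- renderContactVolume(tr)
  s <- vol$surface
  expect_equal(surfaceCoverage(s, s, 0), 100)
  expect_equal(surfaceCoverage(s, s, 5), 100)
  far <- array(FALSE, dim(s@mask)); far[1:2, 1:2, 1:2] <- TRUE
  expect_lt(surfaceCoverage(s, SurfaceMask3D(far, s@voxelSize), 0.6), 1)
  covs <- vapply(c(0.5, 1, 2, 4),
                 function(r) surfaceCoverage(s, SurfaceMask3D(far, s@voxelSize), r),
                 numeric(1))
  expect_true(all(diff(covs) >= 0))
  expect_error(surfaceCoverage(SurfaceMask3D(array(FALSE, c(4, 4, 4)),
                                             c(1, 1, 1)), s), "empty")
})

test_that("a half-wrapping sheath covers about half the tube", {
  vx <- c(0.25, 0.25, 0.25)
  dims <- c(40L, 64L, 64L)
  ext <- dims * vx
  cx <- (seq_len(dims[2]) - 0.5) * vx[2] - ext[2] / 2
  cz <- (seq_len(dims[3]) - 0.5) * vx[3] - ext[3] / 2
  rad <- outer(cx, cz, function(a, b) sqrt(a^2 + b^2))
  tube <- array(rep(rad <= 3, each = dims[1]) > 0, dims)
  sheath2d <- rad > 3 & rad <= 4 &
    outer(cx, cz, function(a, b) b > 0)   # upper half only
  sheath <- array(rep(sheath2d, each = dims[1]) > 0, dims)
  cov <- surfaceCoverage(SurfaceMask3D(tube, vx),
                         SurfaceMask3D(sheath, vx),
                         contactRadiusUm = 1)
  expect_gt(cov, 40); expect_lt(cov, 60)
})

test_that("nucleus-proximal puncta are assigned to unique cells", {
  vx <- c(0.5, 0.5, 0.5)
  dims <- c(64L, 64L, 16L)
  lab <- array(0L, dims)
  lab[6:10, 6:10, 6:10] <- 1L      # nucleus centres ~ (4, 4, 4) um
  lab[30:34, 30:34, 6:10] <- 2L
  lab[50:54, 50:54, 6:10] <- 3L
  centerOf <- function(i0) (i0 + 1.5) * 0.5
  mk <- function(n, cx, cy, spread = 2)
    cbind(cx + seq(0, spread, length.out = n), cy, 4)
  centers <- rbind(mk(2, centerOf(6), centerOf(6)),
                   mk(4, centerOf(30), centerOf(30)),
                   mk(6, centerOf(50), centerOf(50)),
                   c(4, 25, 4))          # 10+ um from all nuclei
  spots <- new("SpotSet", centers = centers,
               quality = rep(1, nrow(centers)),
               diameters = c(0.6, 0.6, 1.2))
  counts <- nucleusProximalPuncta(spots, lab, vx, cutoffUm = 5)
  expect_equal(unname(counts), c(2L, 4L, 6L))
  over <- list(lab == 1, lab >= 1)       # overlapping masks
  expect_error(nucleusProximalPuncta(spots, over, vx), "overlapping")
})

test_that("count normalization always has mean one", {
  expect_equal(normalizePunctaCounts(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(normalizePunctaCounts(rep(3, 4)), rep(1, 4))
  expect_equal(normalizePunctaCounts(7), 1)
  set.seed(10)
  for (i in 1:20) {
    x <- rpois(sample(1:12, 1), 5) + 1
    expect_equal(mean(normalizePunctaCounts(x)), 1)
  }
  expect_error(normalizePunctaCounts(c(0, 0)), "zero")
  expect_error(normalizePunctaCounts(numeric(0)), "at least one")
})
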