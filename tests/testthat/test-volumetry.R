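# Mixture inversion, slice integration, ROI statistics and calibration.

test_that("objectFraction inverts the two-material mixture", {
  m <- trueMaterials()
  expect_identical(objectFraction(-149.7, m), 0)   # pure background
  expect_identical(objectFraction(119.9, m), 1)    # pure object
  expect_equal(objectFraction(-14.9, m), 0.5)      # exact midpoint
  # linearity in the mean: fraction of a mixture mean is the mixture of
  # fractions
  mus <- seq(-149.7, 119.9, length.out = 7)
  expect_equal(objectFraction(mean(mus), m), mean(objectFraction(mus, m)))
  # out-of-range means propagate unclamped
  expect_lt(objectFraction(-160, m), 0)
  expect_gt(objectFraction(125, m), 1)
})

test_that("degenerate material pairs are rejected", {
  expect_error(materialPair(100, 100), "differ")
  expect_error(materialPair(1, -1, sdObject = -2), "SD")
})

test_that("totalVolume integrates per-slice fractions", {
  m <- trueMaterials()
  one <- data.frame(slice_index = 1L, area_mm2 = 1000, mean_hu = -14.9,
                    sd_hu = 0)
  expect_equal(volumeCm3(totalVolume(one, m, 5)), 2.5)
  # additivity over identical disjoint slices
  two <- rbind(one, transform(one, slice_index = 2L))
  expect_equal(volumeCm3(totalVolume(two, m, 5)), 5)
  # linearity in thickness
  expect_equal(volumeCm3(totalVolume(two, m, 2.5)),
               volumeCm3(totalVolume(two, m, 5)) / 2)
  # per-slice components retained and consistent
  res <- totalVolume(two, m, 5)
  expect_length(sliceFractions(res), 2)
  expect_equal(sum(sliceVolumes(res)), volumeCm3(res))
  # out-of-range diagnostic
  noisy <- data.frame(slice_index = 1:2, area_mm2 = 100,
                      mean_hu = c(-155, -149.7), sd_hu = 0)
  expect_identical(outOfRangeSlices(totalVolume(noisy, m, 5)), 1L)
})

test_that("totalVolume rejects invalid inputs", {
  m <- trueMaterials()
  empty <- data.frame(slice_index = integer(), area_mm2 = numeric(),
                      mean_hu = numeric(), sd_hu = numeric())
  expect_error(totalVolume(empty, m, 5), "empty")
  ok <- data.frame(slice_index = 1L, area_mm2 = 10, mean_hu = 0, sd_hu = 0)
  expect_error(totalVolume(ok, m, 0), "positive")
  expect_error(totalVolume(ok, m, -5), "positive")
  dup <- rbind(ok, ok)
  expect_error(totalVolume(dup, m, 5), "unique")
  bad <- transform(ok, area_mm2 = -1)
  expect_error(totalVolume(bad, m, 5), "positive")
})

test_that("totalVolume recovers a voxelized sphere against the closed form", {
  # fine through-plane sampling: > 100 slices contain the sphere
  sph <- singleSphere(pixelMm = 0.27, thinMm = 0.09)
  res <- phantomVolumetry(sph$hu, sph$occupancy, trueMaterials())
  expect_gt(nrow(measurements(res)), 100)
  expect_lt(abs(volumeCm3(res) - 4 / 3 * pi * 5^3 / 1000), 0.005 * 0.5235988)
})

test_that("background growth leaves the area-fraction product invariant", {
  m <- trueMaterials()
  a <- 0.25  # pixel area mm^2
  n <- 400
  mu <- -40
  A0 <- n * a
  f0 <- objectFraction(mu, m)
  for (k in c(1, 10, 1000)) {
    muK <- (n * mu + k * huBackground(m)) / (n + k)
    AK <- (n + k) * a
    expect_equal(AK * objectFraction(muK, m), A0 * f0, tolerance = 1e-12)
  }
})

test_that("relativeError is signed and exact on proportional offsets", {
  expect_equal(relativeError(35.5, 35.5), 0)
  expect_equal(round(relativeError(34.6, 35.5), 1), -2.5)
  for (x in c(-0.2, -0.01, 0.03, 0.5))
    expect_equal(relativeError(35.5 * (1 + x), 35.5), 100 * x,
                 tolerance = 1e-12)
  expect_error(relativeError(10, 0), "positive")
  expect_error(relativeError(10, -3), "positive")
})

test_that("measureROI reports mean, population SD and metric area", {
  vol <- flatVolume(dim = c(20, 20, 3))
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE  # 100 pixels at 0.5 x 0.5 mm
  r <- measureROI(vol, mask, sliceIndex = 2)
  expect_equal(r$area_mm2, 25)
  expect_equal(r$mean_hu, -149.7)
  expect_equal(r$sd_hu, 0)
  # half object / half background averages to the midpoint
  v2 <- vol
  arr <- gridValues(v2)
  arr[1:10, 1:5, 2] <- 119.9
  v2 <- CTVolume(arr, voxelSpacing(vol))
  expect_equal(measureROI(v2, mask, sliceIndex = 2)$mean_hu, -14.9)
  # population SD convention (divide by n)
  v3 <- CTVolume(array(c(0, 2, 0, 2), c(2, 2, 1)), c(1, 1, 1))
  expect_equal(measureROI(v3, matrix(TRUE, 2, 2), 1)$sd_hu, 1)
})

test_that("measureROI recovers the injected noise SD on a large mask", {
  vol <- addNoise(flatVolume(dim = c(100, 100, 1)), 4.6, seed = 11)
  r <- measureROI(vol, matrix(TRUE, 100, 100), 1)
  expect_lt(abs(r$sd_hu - 4.6) / 4.6, 0.03)  # 10^4 samples
  expect_lt(abs(r$mean_hu + 149.7), 3 * 4.6 / 100)
})

test_that("measureROI rejects bad masks", {
  vol <- flatVolume()
  expect_error(measureROI(vol, matrix(FALSE, 20, 20), 1), "empty")
  expect_error(measureROI(vol, matrix(TRUE, 5, 5), 1), "dimensions")
  expect_error(measureROI(vol, matrix(TRUE, 20, 20), 99), "outside")
  expect_error(measureROI(vol, matrix(TRUE, 20, 20)), "sliceIndex")
})

test_that("calibration is exact on a noise-free phantom", {
  fx <- smallPhantom()
  mat <- calibratePhantom(fx$hu, fx$occ, fx$pack, seed = 3)
  expect_equal(huObject(mat), 119.9)
  expect_equal(huBackground(mat), -149.7)
  expect_equal(sdObject(mat), 0)
  expect_equal(sdBackground(mat), 0)
})

test_that("calibration on a noisy phantom lands within sampling error", {
  fx <- smallPhantom()
  noisy <- addNoise(fx$hu, 5.3, seed = 21)
  mat <- calibratePhantom(noisy, fx$occ, fx$pack, seed = 3)
  expect_lt(abs(huObject(mat) - 119.9), 2)
  expect_lt(abs(huBackground(mat) + 149.7), 0.5)  # ~10 cm^2 ROI
  expect_lt(abs(sdBackground(mat) - 5.3), 0.5)
})

test_that("calibration warns when an object ROI leaks into background", {
  fx <- smallPhantom()
  rois <- autoCalibrationROIs(fx$occ, fx$pack, seed = 3)
  # enlarge one bead ROI until it must cover partial-volume pixels
  bad <- rois$objects[[1]]
  bigger <- ctvolumetry:::.dilateMm(bad@mask, 3, voxelSpacing(fx$hu)[1],
                                    voxelSpacing(fx$hu)[2])
  rois$objects[[1]] <- sliceROI(bad@sliceIndex, bigger, "object_cal")
  expect_warning(
    calibrateMaterials(fx$hu, rois$background, rois$objects,
                       occupancy = fx$occ),
    "overlaps background")
  expect_error(calibrateMaterials(fx$hu, rois$background, list()),
               "at least one")
})

test_that("cnr divides contrast by the noise SD", {
  m <- trueMaterials()
  expect_equal(cnr(materialPair(100, 0), 10), 10)
  expect_equal(round(cnr(m, 22.3), 1), 12.1)
  expect_error(cnr(m, 0), "positive")
  expect_error(cnr(m, -1), "positive")
})
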