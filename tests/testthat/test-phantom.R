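# Sphere packing, voxelization and the acquisition emulation operators.

test_that("packBeads places non-overlapping spheres inside the container", {
  p <- packBeads(150, container = c(45, 45, 30), seed = 5)
  expect_gte(length(p), 75)
  ctr <- beadCenters(p); r <- beadRadii(p)
  # brute-force O(n^2) pairwise overlap check
  dmin <- Inf
  for (i in seq_len(length(p) - 1)) {
    j <- (i + 1):length(p)
    gap <- sqrt((ctr[j, 1] - ctr[i, 1])^2 + (ctr[j, 2] - ctr[i, 2])^2 +
                  (ctr[j, 3] - ctr[i, 3])^2) - (r[j] + r[i])
    dmin <- min(dmin, gap)
  }
  expect_gte(dmin, -1e-6)  # tangency tolerance
  # containment
  for (a in 1:3) {
    expect_true(all(ctr[, a] - r >= -1e-9))
    expect_true(all(ctr[, a] + r <= c(45, 45, 30)[a] + 1e-9))
  }
})

test_that("packBeads is deterministic and honours edge cases", {
  p1 <- packBeads(30, container = c(30, 30, 20), seed = 9)
  p2 <- packBeads(30, container = c(30, 30, 20), seed = 9)
  expect_identical(beadCenters(p1), beadCenters(p2))
  expect_identical(beadRadii(p1), beadRadii(p2))
  single <- packBeads(1, container = c(10, 10, 10), seed = 1)
  expect_identical(length(single), 1L)
  expect_error(packBeads(500, container = c(12, 12, 12), seed = 1),
               "packing failed")
  expect_error(packBeads(5, container = c(5, 5, 5), seed = 1), "fit")
})

test_that("the default 750-bead pack approximates the physical reference volume", {
  p <- packBeads(750, seed = 42)
  expect_identical(length(p), 750L)
  # diameter mix calibrated so the pack lands near 35.5 cm^3
  expect_lt(abs(analyticVolume(p) - 35.5), 2)
})

test_that("analyticVolume matches the closed form", {
  one <- beadPack(matrix(c(5, 5, 5), 1), 5, c(10, 10, 10))
  expect_equal(analyticVolume(one), 4 / 3 * pi * 125 / 1000,
               tolerance = 1e-12)
  two <- beadPack(rbind(c(3, 3, 3), c(12, 12, 12)), c(2.5, 2.5),
                  c(16, 16, 16))
  expect_equal(analyticVolume(two), 2 * 4 / 3 * pi * 2.5^3 / 1000)
})

test_that("voxelization reproduces pure-material voxels and the mixture map", {
  fx <- smallPhantom()
  occ <- gridValues(fx$occ)
  hu <- gridValues(fx$hu)
  expect_true(all(occ >= 0 & occ <= 1))
  expect_identical(hu[occ == 1][1], 119.9)
  expect_identical(hu[occ == 0][1], -149.7)
  # weighted-average relation holds voxel-wise
  expect_equal(hu, 119.9 * occ + (-149.7) * (1 - occ))
})

test_that("occupancy sum converges to the analytic sphere volume", {
  sph <- singleSphere(pixelMm = 0.27, thinMm = 0.27, supersampling = 4L)
  est <- sum(gridValues(sph$occupancy)) * voxelVolumeMm3(sph$occupancy)
  expect_lt(abs(est / (4 / 3 * pi * 125) - 1), 0.002)
  # finer supersampling tightens the estimate
  sph8 <- singleSphere(pixelMm = 0.27, thinMm = 0.27, supersampling = 8L)
  est8 <- sum(gridValues(sph8$occupancy)) * voxelVolumeMm3(sph8$occupancy)
  expect_lte(abs(est8 / (4 / 3 * pi * 125) - 1),
             abs(est / (4 / 3 * pi * 125) - 1) + 1e-6)
})

test_that("voxelize rejects spheres outside the grid", {
  pack <- beadPack(matrix(c(5, 5, 5), 1), 4.9, c(10, 10, 10))
  grid <- list(dim = c(10L, 10L, 10L), spacing = c(0.5, 0.5, 0.5),
               origin = c(0, 0, 0))
  expect_error(voxelize(pack, acquisitionConfig(), grid = grid), "outside")
})

test_that("reslice block-averages and preserves the volume mean", {
  v <- CTVolume(array(seq_len(4 * 4 * 8), c(4, 4, 8)),
                spacing = c(1, 1, 0.625))
  expect_identical(reslice(v, 0.625), v)  # identity at native spacing
  r <- reslice(v, 5)
  expect_identical(dim(r)[3], 1L)
  expect_equal(voxelSpacing(r)[3], 5)
  # one 5 mm slice = mean of the 8 native slices, voxel-wise
  expect_equal(gridValues(r)[, , 1],
               apply(gridValues(v), c(1, 2), mean))
  expect_equal(mean(gridValues(r)), mean(gridValues(v)), tolerance = 1e-12)
  expect_error(reslice(v, 1), "integer multiple")
  expect_error(reslice(v, 0.625 * 3), "divisible")
})

test_that("addNoise is zero-mean, deterministic and exact at sd = 0", {
  v <- flatVolume(dim = c(50, 50, 40))  # 10^5 voxels
  expect_identical(addNoise(v, 0, seed = 1), v)
  n1 <- addNoise(v, 22.3, seed = 4)
  n2 <- addNoise(v, 22.3, seed = 4)
  expect_identical(gridValues(n1), gridValues(n2))
  resid <- gridValues(n1) - gridValues(v)
  expect_lt(abs(sd(resid) - 22.3) / 22.3, 0.01)
  expect_lt(abs(mean(resid)), 3 * 22.3 / sqrt(length(resid)))
  expect_false(identical(gridValues(addNoise(v, 22.3, seed = 5)),
                         gridValues(n1)))
})

test_that("edgeEnhance preserves flat fields and overshoots at edges", {
  v <- flatVolume(dim = c(30, 30, 2))
  expect_identical(edgeEnhance(v, strength = 0), v)
  e <- edgeEnhance(v, strength = 1.5, radiusMm = 0.8)
  expect_equal(gridValues(e), gridValues(v), tolerance = 1e-12)
  # step edge along axis 1: compare against an independent 1-D convolution
  step <- array(rep(c(rep(-149.7, 20), rep(119.9, 20)), 40), c(40, 40, 1))
  sv <- CTVolume(step, spacing = c(0.5, 0.5, 1))
  es <- gridValues(edgeEnhance(sv, strength = 1, radiusMm = 0.8))
  prof <- es[, 20, 1]
  sigma <- 0.8 / 0.5
  h <- ceiling(3 * sigma)
  w <- dnorm(-h:h, sd = sigma); w <- w / sum(w)
  x <- step[, 20, 1]
  xp <- c(rep(x[1], h), x, rep(x[40], h))
  blur <- vapply(seq_len(40), function(i) sum(w * xp[i:(i + 2 * h)]), 0)
  expect_equal(prof[(h + 1):(40 - h)], (2 * x - blur)[(h + 1):(40 - h)],
               tolerance = 1e-10)
  expect_gt(max(prof), 119.9)  # overshoot
  expect_lt(min(prof), -149.7) # undershoot
})

test_that("reformat permutes axes and preserves values", {
  fx <- smallPhantom()
  cor <- reformat(fx$hu, "coronal")
  expect_equal(mean(gridValues(cor)), mean(gridValues(fx$hu)))
  expect_identical(gridValues(reformat(cor, "coronal")), gridValues(fx$hu))
  expect_identical(voxelSpacing(reformat(cor, "coronal")),
                   voxelSpacing(fx$hu))
  sag <- reformat(fx$hu, "sagittal")
  expect_equal(mean(gridValues(sag)), mean(gridValues(fx$hu)))
  # sagittal is a cyclic axis permutation: three applications are identity
  expect_identical(gridValues(reformat(reformat(sag, "sagittal"),
                                       "sagittal")),
                   gridValues(fx$hu))
  # reformat volumetry agrees with axial volumetry (noise-free)
  m <- trueMaterials()
  vAx <- volumeCm3(phantomVolumetry(fx$hu, fx$occ, m))
  occC <- reformat(fx$occ, "coronal")
  vCo <- volumeCm3(phantomVolumetry(cor, occC, m))
  expect_lt(abs(vCo - vAx) / vAx, 0.01)
})

test_that("resamplePixels block-averages and only coarsens", {
  v <- CTVolume(array(c(1, 2, 3, 4), c(2, 2, 1)), spacing = c(1, 1, 1))
  expect_identical(resamplePixels(v, 1), v)
  r <- resamplePixels(v, 2)
  expect_equal(dim(r)[1:2], c(1L, 1L))
  expect_equal(gridValues(r)[1, 1, 1], 2.5)
  expect_error(resamplePixels(v, 0.5), "coarsening")
  # non-integer factor: global mean still preserved
  fx <- smallPhantom()
  rs <- resamplePixels(fx$hu, voxelSpacing(fx$hu)[1] * 50 / 14)
  expect_equal(mean(gridValues(rs)), mean(gridValues(fx$hu)),
               tolerance = 1e-9)
  # volumetry at coarse pixels still matches (background-growth invariance
  # extends to in-plane averaging)
  occC <- resamplePixels(fx$occ, voxelSpacing(fx$occ)[1] * 50 / 14)
  m <- trueMaterials()
  vFine <- volumeCm3(phantomVolumetry(fx$hu, fx$occ, m))
  vCoarse <- volumeCm3(phantomVolumetry(rs, occC, m))
  expect_lt(abs(vCoarse - vFine) / vFine, 0.01)
})

test_that("identical seeds reproduce bit-identical phantoms", {
  cfg <- acquisitionConfig()
  p1 <- packBeads(25, container = c(25, 25, 18), seed = 13)
  p2 <- packBeads(25, container = c(25, 25, 18), seed = 13)
  v1 <- addNoise(voxelize(p1, cfg)$hu, 4.6, seed = 13)
  v2 <- addNoise(voxelize(p2, cfg)$hu, 4.6, seed = 13)
  expect_identical(gridValues(v1), gridValues(v2))
})
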