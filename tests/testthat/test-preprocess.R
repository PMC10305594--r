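test_that("clipHU clamps out-of-window voxels and keeps in-range ones", {
  v <- CTVolume(array(c(1000, -1024, 0, 499.5), c(4, 1, 1)))
  out <- voxelData(clipHU(v))
  expect_equal(as.numeric(out), c(500, -800, 0, 499.5))
  expect_error(clipHU(v, 100, -100), "low must be <")
})

test_that("normalizeIntensity maps the window linearly onto [0, 1]", {
  v <- CTVolume(array(c(-800, 500, -150), c(3, 1, 1)))
  out <- voxelData(normalizeIntensity(v))
  expect_equal(as.numeric(out), c(0, 1, 0.5))  # (-150 + 800) / 1300 = 0.5
  expect_error(normalizeIntensity(CTVolume(array(600, c(1, 1, 1)))),
               "clip first")
})

test_that("clip then normalize maps any real grid into [0, 1]", {
  set.seed(99)
  for (i in 1:10) {
    v <- CTVolume(array(rnorm(5 * 4 * 3, sd = 2000), c(5, 4, 3)))
    out <- voxelData(normalizeIntensity(clipHU(v)))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("extractPatches yields the configured count, shape and coverage", {
  ph <- tinyPhantom(seed = 2L, shape = c(40L, 40L, 12L))
  cfg <- preprocessConfig(patchXY = 24L, patchesPerVolume = 9L, seed = 5L)
  ps <- extractPatches(ph$volume, cfg)
  expect_equal(nPatches(ps), 9L)
  for (r in patchRecords(ps)) {
    expect_equal(dim(r@patch), c(24L, 24L, 12L))
    expect_true(all(r@origin >= 0L))
    expect_true(all(r@origin + dim(r@patch) <= r@sourceShape))
  }
  cov <- matrix(FALSE, 40, 40)
  for (r in patchRecords(ps))
    cov[r@origin[1] + 1:24, r@origin[2] + 1:24] <- TRUE
  expect_true(all(cov))
})

test_that("patch origins are reproducible for a seed and differ across seeds", {
  ph <- tinyPhantom(seed = 2L, shape = c(40L, 40L, 12L))
  o1 <- patchOrigins(extractPatches(ph$volume,
                                    preprocessConfig(patchXY = 24L, seed = 5L)))
  o2 <- patchOrigins(extractPatches(ph$volume,
                                    preprocessConfig(patchXY = 24L, seed = 5L)))
  o3 <- patchOrigins(extractPatches(ph$volume,
                                    preprocessConfig(patchXY = 24L, seed = 6L)))
  expect_identical(o1, o2)
  expect_false(identical(o1, o3))
})

test_that("a patch the size of the volume degenerates to the identity", {
  ph <- tinyPhantom(seed = 3L, shape = c(16L, 16L, 10L))
  ps <- extractPatches(ph$volume,
                       preprocessConfig(patchXY = 16L, patchesPerVolume = 1L))
  expect_equal(nPatches(ps), 1L)
  r <- patchRecords(ps)[[1]]
  expect_identical(r@origin, c(0L, 0L, 0L))
  expect_equal(r@patch, voxelData(ph$volume))
})

test_that("volumes smaller than the patch are rejected", {
  ph <- tinyPhantom(seed = 3L, shape = c(16L, 16L, 10L))
  expect_error(extractPatches(ph$volume, preprocessConfig(patchXY = 32L)),
               "smaller than patch")
})

test_that("preprocessScan aligns image and mask patches and keeps masks binary", {
  ph <- tinyPhantom(seed = 8L, shape = c(32L, 32L, 12L))
  cfg <- preprocessConfig(patchXY = 16L, seed = 2L)
  pp <- preprocessScan(ph$volume, ph$mask, cfg)
  expect_identical(patchOrigins(pp$image), patchOrigins(pp$mask))
  for (r in patchRecords(pp$image))
    expect_true(all(r@patch >= 0 & r@patch <= 1))
  for (r in patchRecords(pp$mask))
    expect_true(all(r@patch %in% c(0L, 1L)))
  bad <- BinaryMask(array(0L, c(8L, 8L, 8L)))
  expect_error(preprocessScan(ph$volume, bad, cfg), "does not match")
})
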