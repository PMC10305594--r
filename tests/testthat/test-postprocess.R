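test_that("extract -> reconstruct is the exact identity wherever defined", {
  for (s in 1:4) {
    ph <- tinyPhantom(seed = s, shape = c(24L, 24L, 10L))
    cfg <- preprocessConfig(patchXY = 12L, patchesPerVolume = 9L,
                            seed = s + 100L)
    pp <- preprocessScan(ph$volume, ph$mask, cfg)
    recImg <- reconstructVolume(pp$image)
    refImg <- voxelData(normalizeIntensity(clipHU(ph$volume)))
    expect_equal(recImg, refImg, tolerance = 1e-12)
    recMask <- reconstructVolume(pp$mask)
    expect_identical(array(as.integer(recMask), dim(recMask)),
                     voxelData(ph$mask))
  }
})

test_that("overlapping patches are fused by averaging", {
  mk <- function(val, origin) {
    new("PatchRecord", patch = array(val, c(4, 4, 2)),
        origin = as.integer(origin), sourceShape = c(6L, 4L, 2L),
        sourceId = "s")
  }
  ps <- new("PatchSet", records = list(mk(0, c(0, 0, 0)), mk(1, c(2, 0, 0))),
            config = NULL)
  rec <- reconstructVolume(ps)
  expect_equal(unique(as.vector(rec[1:2, , ])), 0)
  expect_equal(unique(as.vector(rec[3:4, , ])), 0.5)  # covered by both
  expect_equal(unique(as.vector(rec[5:6, , ])), 1)
})

test_that("a single full-volume patch reconstructs to itself and gaps error", {
  p <- array(runif(4 * 4 * 3), c(4, 4, 3))
  full <- new("PatchRecord", patch = p, origin = c(0L, 0L, 0L),
              sourceShape = c(4L, 4L, 3L), sourceId = "s")
  expect_equal(reconstructVolume(new("PatchSet", records = list(full),
                                     config = NULL)), p)
  part <- new("PatchRecord", patch = p[1:2, , , drop = FALSE],
              origin = c(0L, 0L, 0L), sourceShape = c(4L, 4L, 3L),
              sourceId = "s")
  expect_error(reconstructVolume(new("PatchSet", records = list(part),
                                     config = NULL)), "not covered")
})

test_that("binarize uses a strict inequality at the threshold", {
  expect_equal(sum(voxelData(binarize(array(0.9, c(3, 3, 3))))), 27L)
  expect_equal(sum(voxelData(binarize(array(0.5, c(3, 3, 3))))), 0L)
  set.seed(2)
  pr <- array(runif(6 * 6 * 6), c(6, 6, 6))
  expect_equal(sum(voxelData(binarize(pr, 0.5))), sum(pr > 0.5))
  expect_error(binarize(array(1.5, c(2, 2, 2))), "\\[0, 1\\]")
})

test_that("small components are removed and large ones kept, idempotently", {
  m <- array(0L, c(12, 12, 6))
  m[2:6, 2:6, 2:5] <- 1L            # 100 voxels
  m[10, 10, c(1, 2, 3)] <- 1L       # 3 voxels
  cfg <- postprocessConfig(minComponentVoxels = 10L)
  out <- removeSmallComponents(m, cfg)
  expect_equal(sum(out), 100L)
  expect_identical(removeSmallComponents(out, cfg), out)
  small <- array(0L, c(6, 6, 6)); small[1:3, 1, 1] <- 1L
  expect_equal(sum(removeSmallComponents(small, cfg)), 0L)
  empty <- array(0L, c(6, 6, 6))
  expect_identical(removeSmallComponents(empty, cfg), empty)
})

test_that("hole filling closes interior cavities but not the background", {
  m <- array(0L, c(10, 10, 10))
  m[2:8, 2:8, 2:8] <- 1L
  m[5, 5, 5] <- 0L  # 1-voxel interior hole
  out <- removeSmallComponents(m, postprocessConfig(minComponentVoxels = 8L))
  expect_equal(out[5, 5, 5], 1L)
  expect_equal(out[1, 1, 1], 0L)
  noFill <- removeSmallComponents(
    m, postprocessConfig(minComponentVoxels = 8L, fillHoles = FALSE))
  expect_equal(noFill[5, 5, 5], 0L)
})

test_that("component filtering never adds foreground outside holes", {
  set.seed(6)
  for (i in 1:5) {
    m <- randomMask(c(10, 10, 8), 0.1)
    out <- removeSmallComponents(
      m, postprocessConfig(minComponentVoxels = 5L, fillHoles = FALSE))
    expect_true(all(out <= m))
    expect_identical(
      removeSmallComponents(out, postprocessConfig(minComponentVoxels = 5L,
                                                   fillHoles = FALSE)), out)
  }
})
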