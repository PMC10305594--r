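test_that("phantoms are bit-identical for a seed and differ across seeds", {
  a <- tinyPhantom(seed = 5L, shape = c(24L, 24L, 16L))
  b <- tinyPhantom(seed = 5L, shape = c(24L, 24L, 16L))
  c_ <- tinyPhantom(seed = 6L, shape = c(24L, 24L, 16L))
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(voxelData(a$mask), voxelData(b$mask))
  expect_false(identical(voxelData(a$volume), voxelData(c_$volume)))
})

test_that("the arterial tree is one 26-connected component with small volume", {
  for (s in c(1L, 9L, 23L)) {
    ph <- tinyPhantom(seed = s, shape = c(32L, 32L, 24L))
    m <- voxelData(ph$mask)
    lab <- druseg:::label_components_cpp(m, dim(m), 26L)
    expect_equal(max(lab), 1L)
    expect_lt(mean(m), 0.05)  # class imbalance the Dice term targets
    expect_gt(sum(m), 0L)
  }
})

test_that("tissue intensities land near their configured HU values", {
  spec <- phantomSpec(shape = c(48L, 48L, 24L), seed = 3L)
  ph <- generatePhantom(spec)
  img <- voxelData(ph$volume)
  m <- voxelData(ph$mask) == 1L
  nVessel <- sum(m)
  # sd of the sample mean: sqrt(sd_tissue^2 + noise^2) / sqrt(n)
  se <- sqrt(spec@vesselHU[2]^2 + spec@noiseSD^2) / sqrt(nVessel)
  expect_lt(abs(mean(img[m]) - spec@vesselHU[1]), 3 * se + 1e-9)
  # the bulk of the background sits near lung attenuation
  expect_lt(median(img[!m]), -700)
})

test_that("vessel/background contrast survives clipping and normalization", {
  for (s in 1:5) {
    ph <- tinyPhantom(seed = s, shape = c(32L, 32L, 16L))
    v <- normalizeIntensity(clipHU(ph$volume))
    img <- voxelData(v)
    m <- voxelData(ph$mask) == 1L
    lung <- img < 0.3 & !m
    expect_gte(mean(img[m]) - mean(img[lung]), 0.3)
  }
})

test_that("generateDataset writes readable pairs and a complete manifest", {
  dir <- withr::local_tempdir()
  man <- generateDataset(3L, phantomSpec(shape = c(16L, 16L, 12L), seed = 2L),
                         dir, split = c("train", "train", "test"))
  expect_equal(nrow(man), 3L)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  expect_equal(man$split, c("train", "train", "test"))
  onDisk <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE)
  expect_equal(onDisk$id, man$id)
  v <- readScan(man$image_path[1])
  m <- readScan(man$mask_path[1], mask = TRUE)
  expect_equal(dim(voxelData(v)), c(16L, 16L, 12L))
  expect_equal(dim(voxelData(m)), c(16L, 16L, 12L))
})
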