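test_that("NIfTI write -> read is the identity on data, spacing and affine", {
  ph <- tinyPhantom(seed = 21L, shape = c(16L, 16L, 12L))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeScan(ph$volume, f)
  rv <- readScan(f)
  # NIfTI headers store pixdim as 32-bit floats
  expect_equal(voxelSpacing(rv), c(0.7, 0.7, 1.0), tolerance = 1e-6)
  # HU grids are stored as 32-bit floats
  expect_equal(voxelData(rv), voxelData(ph$volume), tolerance = 1e-6)
  expect_equal(rv@affine, ph$volume@affine, tolerance = 1e-5)

  fm <- withr::local_tempfile(fileext = ".nii.gz")
  writeScan(ph$mask, fm)
  rm_ <- readScan(fm, mask = TRUE)
  expect_s4_class(rm_, "BinaryMask")
  expect_identical(voxelData(rm_), voxelData(ph$mask))
})

test_that("a clipped volume survives the round trip with its bounds intact", {
  ph <- tinyPhantom(seed = 4L, shape = c(16L, 16L, 12L))
  v <- clipHU(ph$volume)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeScan(v, f)
  rv <- readScan(f)
  expect_equal(min(voxelData(rv)), -800, tolerance = 1e-5)
  expect_lte(max(voxelData(rv)), 500 + 1e-4)
})

test_that("an all-zero mask reads back with voxel sum zero", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeScan(BinaryMask(array(0L, c(8L, 8L, 8L))), f)
  expect_identical(sum(voxelData(readScan(f, mask = TRUE))), 0L)
})

test_that("malformed inputs are rejected with informative errors", {
  expect_error(readScan(file.path(tempdir(), "no_such_scan.nii.gz")),
               "not found")

  f2d <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 8, 8)), f2d)
  expect_error(readScan(f2d), "3D")

  fnb <- withr::local_tempfile(fileext = ".nii.gz")
  writeScan(CTVolume(array(c(0, 1, 2), c(3, 2, 2))), fnb)
  expect_error(readScan(fnb, mask = TRUE), "outside \\{0, 1\\}")

  expect_error(CTVolume(array(0, c(4, 4, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(BinaryMask(array(2L, c(2, 2, 2))), "non-binary")
})
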