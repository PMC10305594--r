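test_that("dice coefficient matches direct count arithmetic", {
  a <- array(0L, c(4, 4, 1)); b <- a
  a[1:3, 1, 1] <- 1L; a[1, 2:4, 1] <- 1L  # |P| = 6
  b[1:4, 1, 1] <- 1L                      # |G| = 4, |P ∩ G| = 3
  expect_equal(diceCoefficient(a, b), 0.6)

  m <- randomMask(c(5, 5, 5), 0.4)
  expect_equal(diceCoefficient(m, m), 1)
  expect_equal(diceCoefficient(m, array(0L, dim(m))), 0)
  expect_equal(diceCoefficient(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), 1)
  expect_error(diceCoefficient(m, array(0L, c(2, 2, 2))), "differ")
})

test_that("dice coefficient is symmetric", {
  set.seed(12)
  for (i in 1:10) {
    a <- randomMask(c(8, 7, 6), 0.2)
    b <- randomMask(c(8, 7, 6), 0.2)
    expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  }
})

test_that("surface extraction follows the 6-neighbour boundary rule", {
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  expect_equal(nrow(extractSurface(one)@points), 1L)

  cube <- array(0L, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(extractSurface(cube)@points), 26L)  # all but the centre

  sheet <- array(0L, c(6, 6, 3)); sheet[, , 2] <- 1L
  expect_equal(nrow(extractSurface(sheet)@points), 36L)

  edge <- array(1L, c(3, 3, 3))  # grid-edge voxels count as boundary,
  expect_equal(nrow(extractSurface(edge)@points), 26L)  # centre does not

  expect_error(extractSurface(array(0L, c(3, 3, 3))), "empty")
})

test_that("hd95 reproduces hand-computed separations in mm", {
  a <- array(0L, c(12, 4, 4)); b <- a
  a[2, 2, 2] <- 1L; b[7, 2, 2] <- 1L
  expect_equal(hd95(a, b, spacing = c(1, 1, 1)), 5)
  expect_equal(hd95(a, b, spacing = c(0.5, 0.5, 1.0)), 2.5)
  m <- randomMask(c(6, 6, 6), 0.3)
  expect_equal(hd95(m, m, spacing = c(0.7, 0.7, 1)), 0)
  expect_error(hd95(m, array(0L, dim(m))), "empty")
})

test_that("hd95 agrees with the brute-force pairwise oracle", {
  set.seed(31)
  for (i in 1:40) {
    shp <- sample(4:16, 3, replace = TRUE)
    a <- randomMask(shp, runif(1, 0.05, 0.4))
    b <- randomMask(shp, runif(1, 0.05, 0.4))
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- c(runif(2, 0.5, 1), 1)
    expect_equal(hd95(a, b, spacing = sp), bruteForceHD(a, b, sp),
                 tolerance = 1e-9)
    expect_equal(hd95(a, b, spacing = sp, percentile = 100),
                 bruteForceHD(a, b, sp, percentile = 100), tolerance = 1e-9)
  }
})

test_that("the percentile trims outliers and spacing scales linearly", {
  set.seed(17)
  for (i in 1:10) {
    a <- randomMask(c(10, 10, 8), 0.1)
    b <- randomMask(c(10, 10, 8), 0.1)
    if (sum(a) == 0 || sum(b) == 0) next
    h95 <- hd95(a, b)
    expect_gte(hd95(a, b, percentile = 100), h95)
    expect_equal(hd95(a, b, spacing = c(1.7, 1.7, 1.7)),
                 1.7 * hd95(a, b, spacing = c(1, 1, 1)), tolerance = 1e-9)
  }
})

test_that("evaluateSegmentation reports both metrics per scan", {
  ph <- tinyPhantom(seed = 13L, shape = c(16L, 16L, 12L))
  rep_ <- evaluateSegmentation(ph$mask, ph$mask, scanId = "self")
  expect_equal(rep_$dsc, 1)
  expect_equal(rep_$hd95_mm, 0)
  expect_equal(rep_$scan_id, "self")
})
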