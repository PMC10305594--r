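test_that("dice loss matches its closed forms", {
  # perfect binary match: 1 - 2*4/(4+4)
  g <- c(1, 1, 1, 1, 0, 0)
  expect_equal(diceLoss(g, g), 0, tolerance = 1e-6)
  # disjoint non-empty masks
  expect_equal(diceLoss(c(1, 0), c(0, 1)), 1, tolerance = 1e-6)
  # squared-denominator form: 1 - 2*0.5 / (0.25 + 0.25 + 1) = 1/3
  expect_equal(diceLoss(c(0.5, 0.5), c(1, 0)), 1 / 3, tolerance = 1e-5)
  # both empty: perfect agreement on emptiness
  expect_equal(diceLoss(c(0, 0), c(0, 0)), 0)
})

test_that("bce matches its closed forms", {
  expect_equal(bceLoss(rep(0.5, 8), rep(c(0, 1), 4)), log(2), tolerance = 1e-12)
  expect_equal(bceLoss(0.9, 1), -log(0.9), tolerance = 1e-12)
  expect_lt(bceLoss(c(1, 0, 1), c(1, 0, 1)), 1e-6)  # <= -log(1 - clamp)
})

test_that("dbce is exactly the mean of its components", {
  set.seed(3)
  for (i in 1:10) {
    p <- runif(20)
    g <- rbinom(20, 1, 0.3)
    expect_equal(dbceLoss(p, g), (diceLoss(p, g) + bceLoss(p, g)) / 2)
    expect_gte(dbceLoss(p, g), min(diceLoss(p, g), bceLoss(p, g)))
    expect_lte(dbceLoss(p, g), max(diceLoss(p, g), bceLoss(p, g)))
  }
})

test_that("all losses are finite and non-negative on arbitrary valid input", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:50, 1)
    p <- runif(n)
    g <- rbinom(n, 1, runif(1))
    for (v in c(diceLoss(p, g), bceLoss(p, g), dbceLoss(p, g))) {
      expect_true(is.finite(v))
      expect_gte(v, 0)
    }
  }
})

test_that("binary dice loss is one minus the Dice coefficient", {
  set.seed(7)
  for (i in 1:10) {
    a <- randomMask(c(6, 5, 4), 0.3)
    b <- randomMask(c(6, 5, 4), 0.3)
    if (sum(a) + sum(b) == 0) next
    expect_equal(diceLoss(a * 1.0, b), 1 - diceCoefficient(a, b),
                 tolerance = 1e-5)
  }
})

test_that("analytic loss gradients match finite differences on 3-voxel input", {
  set.seed(5)
  p <- c(0.3, 0.6, 0.9)
  g <- c(0, 1, 1)
  eps <- 1e-6
  for (nm in c("dice", "bce", "dbce")) {
    an <- druseg:::lossWithGrad(nm, p, g)$grad
    lossFn <- switch(nm, dice = diceLoss, bce = bceLoss, dbce = dbceLoss)
    for (i in 1:3) {
      pp <- p; pp[i] <- p[i] + eps
      pm <- p; pm[i] <- p[i] - eps
      fd <- (lossFn(pp, g) - lossFn(pm, g)) / (2 * eps)
      expect_equal(an[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("mismatched or invalid loss inputs are rejected", {
  expect_error(diceLoss(c(0.5, 0.5), c(1, 0, 0)), "differ")
  expect_error(bceLoss(c(1.5, 0), c(1, 0)), "\\[0, 1\\]")
  expect_error(diceLoss(c(0.5, 0.5), c(2, 0)), "binary")
})
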