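test_that("forward preserves spatial shape and stays strictly inside (0,1)", {
  net <- buildDRUNet(tinyNetConfig(), seed = 2L)
  set.seed(14)
  for (i in 1:4) {
    shp <- 4L * sample(1:4, 3, replace = TRUE)  # multiples of 2^levels
    x <- array(runif(prod(shp)), shp)
    p <- drunetForward(net, x)
    expect_equal(dim(p), shp)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("indivisible input shapes are rejected with the required factor", {
  net <- buildDRUNet(tinyNetConfig(levels = 2L), seed = 2L)
  expect_error(drunetForward(net, array(0.5, c(10, 10, 10))), "divisible by 4")
})

test_that("forward is deterministic and finite on degenerate input", {
  net <- buildDRUNet(tinyNetConfig(), seed = 3L)
  x <- array(runif(8 * 8 * 8), c(8, 8, 8))
  expect_identical(drunetForward(net, x), drunetForward(net, x))
  p0 <- drunetForward(net, array(0, c(8, 8, 8)))
  expect_true(all(is.finite(p0)))
})

test_that("a levels-1 network round-trips the input shape", {
  net <- buildDRUNet(tinyNetConfig(levels = 1L, baseWidth = 2L, units = 1L),
                     seed = 1L)
  p <- drunetForward(net, array(runif(6 * 6 * 4), c(6, 6, 4)))
  expect_equal(dim(p), c(6L, 6L, 4L))
})

test_that("four transitions down shrink the bottleneck to input/16", {
  net <- buildDRUNet(networkConfig(baseWidth = 2L, levels = 4L,
                                   unitsPerBlock = 1L, gnGroups = 2L),
                     seed = 4L)
  x <- array(runif(32 * 32 * 16), c(1L, 32L, 32L, 16L))
  fw <- druseg:::netForward(net, x, withCache = TRUE)
  bottIn <- fw$cache$bott$feats[[1]]
  expect_equal(dim(bottIn)[2:4], c(32L, 32L, 16L) / 16L)
  expect_equal(dim(fw$p)[2:4], c(32L, 32L, 16L))
})

test_that("transition down halves space and doubles channels; up inverts", {
  f <- array(rnorm(16 * 32 * 32 * 16), c(16, 32, 32, 16))
  d <- transitionDown(f)
  expect_equal(dim(d), c(32L, 16L, 16L, 8L))
  u <- transitionUp(d)
  expect_equal(dim(u), dim(f))
  expect_error(transitionDown(array(0, c(4, 5, 5, 5))), "even")
  expect_error(transitionDown(array(0, c(4, 1, 1, 1))), "even")
})

test_that("parameter count matches a layer-by-layer hand tally", {
  w <- 8L; U <- 4L
  drb <- function(cin, cout) {
    conv <- sum(sapply(seq_len(U), function(u) 27 * (cin + (u - 1) * cout) * cout))
    conv + 2 * cout * U + cin * cout + cout
  }
  td <- function(c_) 8 * c_ * 2 * c_ + 2 * (2 * c_)
  tu <- function(cout) 8 * cout * (2 * cout) + cout
  expected <- drb(1, w) + td(w) +
    drb(2 * w, 2 * w) + td(2 * w) +
    drb(4 * w, 4 * w) +
    tu(2 * w) + drb(4 * w, 2 * w) +
    tu(w) + drb(2 * w, w) +
    (w + 1)
  net <- buildDRUNet(networkConfig(baseWidth = w, levels = 2L,
                                   unitsPerBlock = U), seed = 1L)
  expect_equal(countParameters(net), expected)
})

test_that("every parameter receives gradient signal within 5 random trials", {
  cfg <- tinyNetConfig(levels = 2L, baseWidth = 2L, units = 2L)
  net <- buildDRUNet(cfg, seed = 9L)
  touched <- lapply(net@params, function(p) p != p)  # all-FALSE, same shape
  set.seed(21)
  for (trial in 1:5) {
    # 8x8x8 keeps the bottleneck at 2x2x2, so every kernel offset can see data
    x <- array(runif(8 * 8 * 8), c(1, 8, 8, 8))
    g <- array(rbinom(8 * 8 * 8, 1, 0.3), c(8, 8, 8))
    fw <- druseg:::netForward(net, x, withCache = TRUE)
    lv <- druseg:::lossWithGrad("dbce", array(fw$p, dim(g)), g)
    grads <- druseg:::netBackward(net, fw$cache, array(lv$grad, dim(x)))
    expect_true(all(vapply(grads, function(gr) all(is.finite(gr)), logical(1))))
    for (nm in names(touched))
      touched[[nm]] <- touched[[nm]] | (grads[[nm]] != 0)
  }
  untouched <- names(touched)[!vapply(touched, all, logical(1))]
  expect_identical(untouched, character(0))
})

test_that("network gradients match finite differences end to end", {
  cfg <- networkConfig(baseWidth = 2L, levels = 2L, unitsPerBlock = 2L,
                       gnGroups = 2L, precision = "double")
  net <- buildDRUNet(cfg, seed = 5L)
  set.seed(42)
  x <- array(runif(8 * 8 * 4), c(1, 8, 8, 4))
  g <- array(rbinom(8 * 8 * 4, 1, 0.2), c(8, 8, 4))
  fw <- druseg:::netForward(net, x, withCache = TRUE)
  lv <- druseg:::lossWithGrad("dbce", array(fw$p, dim(g)), g)
  grads <- druseg:::netBackward(net, fw$cache, array(lv$grad, dim(x)))
  lossOf <- function(n) {
    p <- array(druseg:::netForward(n, x)$p, dim(g))
    dbceLoss(p, g)
  }
  eps <- 1e-6
  set.seed(43)
  for (nm in sample(names(net@params), 6)) {
    i <- sample(length(net@params[[nm]]), 1)
    n2 <- net
    n2@params[[nm]][i] <- net@params[[nm]][i] + eps
    lp <- lossOf(n2)
    n2@params[[nm]][i] <- net@params[[nm]][i] - eps
    lm <- lossOf(n2)
    expect_equal(grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip the configuration and parameters", {
  net <- buildDRUNet(tinyNetConfig(), seed = 6L)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  re <- loadCheckpoint(f)
  expect_equal(re@config@baseWidth, net@config@baseWidth)
  expect_identical(re@params, net@params)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  expect_identical(drunetForward(re, x), drunetForward(net, x))
})
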