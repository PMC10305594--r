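# Shared fixtures: everything is generated in code, seeded.

tinyPhantom <- function(seed = 1L, shape = c(32L, 32L, 16L)) {
  generatePhantom(phantomSpec(shape = shape, seed = as.integer(seed)))
}

# a small network that still exercises every layer type
tinyNetConfig <- function(levels = 2L, baseWidth = 4L, units = 2L) {
  networkConfig(baseWidth = as.integer(baseWidth), levels = as.integer(levels),
                unitsPerBlock = as.integer(units), gnGroups = 4L)
}

randomMask <- function(shape, p = 0.15) {
  array(as.integer(stats::runif(prod(shape)) < p), shape)
}

# pure-R brute-force HD oracle: same surface rule, same per-direction
# percentile-then-max convention, O(|X| * |Y|) pairwise distances
bruteForceHD <- function(a, b, spacing = c(1, 1, 1), percentile = 95) {
  surf <- function(m) {
    d <- dim(m)
    pts <- which(m == 1L)
    keep <- vapply(pts, function(s) {
      co <- arrayInd(s, d)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- co
        nb[ax] <- nb[ax] + dd
        if (nb[ax] < 1L || nb[ax] > d[ax]) return(TRUE)
        if (m[nb] == 0L) return(TRUE)
      }
      FALSE
    }, logical(1))
    sweep(arrayInd(pts[keep], d) - 1, 2, spacing, "*")
  }
  A <- surf(a); B <- surf(b)
  D <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  dab <- apply(D, 1, min)
  dba <- apply(D, 2, min)
  max(stats::quantile(dab, percentile / 100, names = FALSE),
      stats::quantile(dba, percentile / 100, names = FALSE))
}
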