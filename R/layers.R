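## Internal layer primitives. Feature tensors are numeric arrays with
## dim = c(C, X, Y, Z) (channel fastest). Convolutions run in compiled code
## (im2col + BLAS); normalization and activations are vectorized R. All
## layers come in fwd/bwd pairs because the optimizer needs exact gradients.

# largest group count <= requested that divides the channel count
gnGroupsFor <- function(channels, requested) {
  g <- min(requested, channels)
  while (channels %% g != 0L) g <- g - 1L
  g
}

catChannels <- function(feats) {
  if (length(feats) == 1L) return(feats[[1]])
  cs <- vapply(feats, function(f) dim(f)[1], integer(1))
  sp <- dim(feats[[1]])[2:4]
  out <- array(0, c(sum(cs), sp))
  at <- 0L
  for (f in feats) {
    out[at + seq_len(dim(f)[1]), , , ] <- f
    at <- at + dim(f)[1]
  }
  out
}

splitChannelGrad <- function(gcat, widths) {
  at <- 0L
  lapply(widths, function(w) {
    g <- gcat[at + seq_len(w), , , , drop = FALSE]
    at <<- at + w
    g
  })
}

lreluFwd <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)
lreluBwd <- function(gout, pre, slope) gout * ((pre > 0) + slope * (pre <= 0))

conv1x1Fwd <- function(x, W, b) {
  d <- dim(x)
  out <- W %*% matrix(x, d[1], prod(d[2:4])) + b
  array(out, c(nrow(W), d[2:4]))
}

conv1x1Bwd <- function(x, W, gout) {
  d <- dim(x)
  gm <- matrix(gout, nrow(W), prod(d[2:4]))
  xm <- matrix(x, d[1], prod(d[2:4]))
  list(gx = array(crossprod(W, gm), d), gW = tcrossprod(gm, xm),
       gb = rowSums(gm))
}

groupNormFwd <- function(z, gamma, beta, groups, eps = 1e-5) {
  d <- dim(z)
  C <- d[1]; V <- prod(d[2:4])
  cg <- C %/% groups
  zm <- matrix(z, C, V)
  xhat <- zm
  invstd <- numeric(groups)
  for (g in seq_len(groups)) {
    idx <- ((g - 1L) * cg + 1L):(g * cg)
    sub <- zm[idx, , drop = FALSE]
    mu <- mean(sub)
    va <- mean(sub * sub) - mu * mu
    invstd[g] <- 1 / sqrt(va + eps)
    xhat[idx, ] <- (sub - mu) * invstd[g]
  }
  out <- array(xhat * gamma + beta, d)
  list(out = out, cache = list(xhat = xhat, invstd = invstd, cg = cg,
                               dims = d))
}

groupNormBwd <- function(gout, cache, gamma) {
  d <- cache$dims
  C <- d[1]; V <- prod(d[2:4])
  gm <- matrix(gout, C, V)
  xhat <- cache$xhat
  dgamma <- rowSums(gm * xhat)
  dbeta <- rowSums(gm)
  dxhat <- gm * gamma
  gz <- dxhat
  cg <- cache$cg
  m <- cg * V
  for (g in seq_along(cache$invstd)) {
    idx <- ((g - 1L) * cg + 1L):(g * cg)
    dh <- dxhat[idx, , drop = FALSE]
    xh <- xhat[idx, , drop = FALSE]
    s1 <- sum(dh); s2 <- sum(dh * xh)
    gz[idx, ] <- cache$invstd[g] * (dh - s1 / m - xh * (s2 / m))
  }
  list(gz = array(gz, d), dgamma = dgamma, dbeta = dbeta)
}

# fan-in scaled normal init adjusted for the leaky rectifier
heInit <- function(rows, cols, fanIn, slope) {
  matrix(rnorm(rows * cols, 0, sqrt(2 / ((1 + slope^2) * fanIn))), rows, cols)
}

## dense residual block: U serial units (conv3 -> GN -> LReLU), unit u
## consuming the channel-concatenation of the block input and all previous
## unit outputs, merged by addition with a 1x1x1-transformed skip path

drbInit <- function(cin, cout, units, gnGroups, slope) {
  p <- list()
  for (u in seq_len(units)) {
    ci <- cin + (u - 1L) * cout
    p[[sprintf("u%d.W", u)]] <- heInit(cout, 27L * ci, 27L * ci, slope)
    p[[sprintf("u%d.g", u)]] <- rep(1, cout)
    p[[sprintf("u%d.b", u)]] <- rep(0, cout)
  }
  p[["skip.W"]] <- heInit(cout, cin, cin, slope)
  p[["skip.b"]] <- rep(0, cout)
  p
}

drbForward <- function(x, P, prefix, units, gnGroups, slope,
                       withCache = FALSE, single = TRUE) {
  feats <- list(x)
  ucache <- if (withCache) vector("list", units) else NULL
  for (u in seq_len(units)) {
    xin <- catChannels(feats)
    W <- P[[paste0(prefix, sprintf(".u%d.W", u))]]
    z <- conv3d_fwd_cpp(xin, dim(xin), W, single)
    groups <- gnGroupsFor(nrow(W), gnGroups)
    gn <- groupNormFwd(z, P[[paste0(prefix, sprintf(".u%d.g", u))]],
                       P[[paste0(prefix, sprintf(".u%d.b", u))]], groups)
    y <- lreluFwd(gn$out, slope)
    if (withCache) ucache[[u]] <- list(gn = gn$cache, pre = gn$out,
                                       groups = groups)
    feats[[u + 1L]] <- y
  }
  skip <- conv1x1Fwd(x, P[[paste0(prefix, ".skip.W")]],
                     P[[paste0(prefix, ".skip.b")]])
  out <- feats[[units + 1L]] + skip
  if (withCache) list(out = out, cache = list(feats = feats, unit = ucache))
  else list(out = out)
}

drbBackward <- function(gout, cache, P, prefix, units, gnGroups, slope,
                        single = TRUE) {
  grads <- list()
  x <- cache$feats[[1]]
  sb <- conv1x1Bwd(x, P[[paste0(prefix, ".skip.W")]], gout)
  grads[[paste0(prefix, ".skip.W")]] <- sb$gW
  grads[[paste0(prefix, ".skip.b")]] <- sb$gb
  gfeats <- vector("list", units + 1L)
  gfeats[[units + 1L]] <- gout
  for (u in rev(seq_len(units))) {
    gy <- gfeats[[u + 1L]]
    uc <- cache$unit[[u]]
    ga <- lreluBwd(gy, uc$pre, slope)
    gnb <- groupNormBwd(ga, uc$gn,
                        P[[paste0(prefix, sprintf(".u%d.g", u))]])
    grads[[paste0(prefix, sprintf(".u%d.g", u))]] <- gnb$dgamma
    grads[[paste0(prefix, sprintf(".u%d.b", u))]] <- gnb$dbeta
    xin <- catChannels(cache$feats[seq_len(u)])
    W <- P[[paste0(prefix, sprintf(".u%d.W", u))]]
    cb <- conv3d_bwd_cpp(xin, dim(xin), W, gnb$gz, single)
    grads[[paste0(prefix, sprintf(".u%d.W", u))]] <- cb$gW
    widths <- vapply(cache$feats[seq_len(u)], function(f) dim(f)[1],
                     integer(1))
    pieces <- splitChannelGrad(cb$gx, widths)
    for (i in seq_len(u)) {
      gfeats[[i]] <- if (is.null(gfeats[[i]])) pieces[[i]]
                     else gfeats[[i]] + pieces[[i]]
    }
  }
  gx <- gfeats[[1]] + sb$gx
  list(gx = gx, grads = grads)
}
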