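## The DRU-Net: `levels` encoder stages (dense residual block + learned
## transition down), a bottleneck block, `levels` decoder stages (transition
## up + skip concatenation + block), and a 1x1x1 convolution with a sigmoid.
## After each transition down every spatial dimension halves and the channel
## count doubles; transitions up invert that.

#' DRUNet: a built network with its parameters
#'
#' @slot config the [NetworkConfig-class] the network was built from.
#' @slot params named list of weight matrices and normalization vectors.
#' @export
setClass("DRUNet", representation(config = "ANY", params = "list"))

setMethod("show", "DRUNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "DRUNet: %d levels, base width %d, %d units/block, %s parameters\n",
    cfg@levels, cfg@baseWidth, cfg@unitsPerBlock,
    format(countParameters(object), big.mark = ",")))
})

# channel schedule: encoder block l maps in -> w*2^(l-1); transitions double
channelPlan <- function(config) {
  w <- config@baseWidth
  L <- config@levels
  encOut <- w * 2^(seq_len(L) - 1L)
  list(encIn = c(config@inChannels, encOut[-L] * 2L),
       encOut = encOut, bottleneck = w * 2^L)
}

#' Build a DRU-Net
#'
#' Instantiates the architecture described by `config`: dense residual
#' blocks of `unitsPerBlock` conv(3x3x3)/group-norm/leaky-ReLU units with a
#' 1x1x1 skip transform, stride-2 2x2x2 convolutions as transitions down,
#' stride-2 2x2x2 transposed convolutions as transitions up, encoder/decoder
#' skip concatenations, and a 1x1x1 + sigmoid head. Weights use fan-in
#' scaled Gaussian initialization (adjusted for the leaky slope).
#'
#' @param config a [NetworkConfig-class].
#' @param seed optional integer; when given, initialization is reproducible
#'   and the caller's RNG state is untouched.
#' @return A [DRUNet-class].
#' @examples
#' net <- buildDRUNet(networkConfig(baseWidth = 4L, levels = 1L,
#'                                  unitsPerBlock = 2L), seed = 1L)
#' countParameters(net)
#' @export
buildDRUNet <- function(config = networkConfig(), seed = NULL) {
  validObject(config)
  build <- function() {
    plan <- channelPlan(config)
    L <- config@levels
    U <- config@unitsPerBlock
    s <- config@lreluSlope
    P <- list()
    addDrb <- function(name, cin, cout) {
      blk <- drbInit(cin, cout, U, config@gnGroups, s)
      names(blk) <- paste0(name, ".", names(blk))
      P[names(blk)] <<- blk
    }
    for (l in seq_len(L)) {
      addDrb(paste0("enc", l), plan$encIn[l], plan$encOut[l])
      cdn <- plan$encOut[l]
      P[[sprintf("td%d.W", l)]] <- heInit(2L * cdn, 8L * cdn, 8L * cdn, s)
      P[[sprintf("td%d.g", l)]] <- rep(1, 2L * cdn)
      P[[sprintf("td%d.b", l)]] <- rep(0, 2L * cdn)
    }
    addDrb("bott", plan$bottleneck, plan$bottleneck)
    for (l in rev(seq_len(L))) {
      cup <- plan$encOut[l] * 2L       # input channels of transition up
      P[[sprintf("tu%d.W", l)]] <- heInit(8L * plan$encOut[l], cup, cup, s)
      P[[sprintf("tu%d.b", l)]] <- rep(0, plan$encOut[l])
      addDrb(paste0("dec", l), 2L * plan$encOut[l], plan$encOut[l])
    }
    P[["head.W"]] <- matrix(rnorm(plan$encOut[1],
                                  sd = sqrt(1 / plan$encOut[1])), 1L)
    P[["head.b"]] <- 0
    new("DRUNet", config = config, params = P)
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Count trainable parameters
#'
#' @param network a [DRUNet-class].
#' @return Total number of scalar parameters.
#' @export
countParameters <- function(network) {
  sum(vapply(network@params, length, numeric(1)))
}

checkDivisible <- function(dims, levels) {
  f <- 2L^levels
  if (any(dims %% f != 0L))
    stop(sprintf(
      "input of %s cannot pass %d transition-down stages: every spatial dimension must be divisible by %d",
      paste(dims, collapse = "x"), levels, f))
}

# full forward pass; x is (1, X, Y, Z); returns probabilities and, when
# requested, the caches needed for the backward pass
netForward <- function(net, x, withCache = FALSE) {
  cfg <- net@config
  P <- net@params
  L <- cfg@levels; U <- cfg@unitsPerBlock; s <- cfg@lreluSlope
  sgl <- identical(cfg@precision, "single")
  checkDivisible(dim(x)[2:4], L)
  encOut <- vector("list", L)
  caches <- list(enc = vector("list", L), td = vector("list", L),
                 tu = vector("list", L), dec = vector("list", L))
  h <- x
  for (l in seq_len(L)) {
    blk <- drbForward(h, P, paste0("enc", l), U, cfg@gnGroups, s, withCache,
                      single = sgl)
    encOut[[l]] <- blk$out
    if (withCache) caches$enc[[l]] <- blk$cache
    td <- tdForward(blk$out, P[[sprintf("td%d.W", l)]],
                    P[[sprintf("td%d.g", l)]], P[[sprintf("td%d.b", l)]],
                    cfg@gnGroups, s, withCache)
    h <- td$out
    if (withCache) caches$td[[l]] <- td$cache
  }
  bott <- drbForward(h, P, "bott", U, cfg@gnGroups, s, withCache,
                     single = sgl)
  h <- bott$out
  for (l in rev(seq_len(L))) {
    up <- convup_fwd_cpp(h, dim(h), P[[sprintf("tu%d.W", l)]]) +
      P[[sprintf("tu%d.b", l)]]
    if (withCache) caches$tu[[l]] <- list(xin = h)
    hcat <- catChannels(list(up, encOut[[l]]))
    blk <- drbForward(hcat, P, paste0("dec", l), U, cfg@gnGroups, s,
                      withCache, single = sgl)
    h <- blk$out
    if (withCache) caches$dec[[l]] <- c(blk$cache, list(xcat = NULL))
  }
  logits <- conv1x1Fwd(h, P[["head.W"]], P[["head.b"]])
  # clamp so saturated logits cannot round to exactly 0 or 1 in floating point
  p <- pmin(pmax(1 / (1 + exp(-logits)), 1e-12), 1 - 1e-12)
  if (withCache)
    list(p = p, cache = list(enc = caches$enc, td = caches$td,
                             tu = caches$tu, dec = caches$dec,
                             bott = bott$cache, encOut = encOut,
                             headIn = h, p = p))
  else list(p = p)
}

tdForward <- function(x, W, gamma, beta, gnGroups, slope, withCache) {
  z <- convdown_fwd_cpp(x, dim(x), W)
  groups <- gnGroupsFor(nrow(W), gnGroups)
  gn <- groupNormFwd(z, gamma, beta, groups)
  y <- lreluFwd(gn$out, slope)
  if (withCache)
    list(out = y, cache = list(xin = x, gn = gn$cache, pre = gn$out))
  else list(out = y)
}

# backward pass; gp is dLoss/dp on the sigmoid output
netBackward <- function(net, cache, gp) {
  cfg <- net@config
  P <- net@params
  L <- cfg@levels; U <- cfg@unitsPerBlock; s <- cfg@lreluSlope
  sgl <- identical(cfg@precision, "single")
  grads <- list()
  glogit <- gp * cache$p * (1 - cache$p)
  hb <- conv1x1Bwd(cache$headIn, P[["head.W"]], glogit)
  grads[["head.W"]] <- hb$gW
  grads[["head.b"]] <- hb$gb
  gh <- hb$gx
  gEnc <- vector("list", L)        # gradient reaching each encoder output
  for (l in seq_len(L)) {
    db <- drbBackward(gh, cache$dec[[l]], P, paste0("dec", l), U,
                      cfg@gnGroups, s, single = sgl)
    grads[names(db$grads)] <- db$grads
    cup <- dim(cache$tu[[l]]$xin)[1] %/% 2L
    pieces <- splitChannelGrad(db$gx, c(cup, cup))
    gEnc[[l]] <- pieces[[2]]
    gup <- pieces[[1]]
    gb <- rowSums(matrix(gup, dim(gup)[1]))
    ub <- convup_bwd_cpp(cache$tu[[l]]$xin, dim(cache$tu[[l]]$xin),
                         P[[sprintf("tu%d.W", l)]], gup)
    grads[[sprintf("tu%d.W", l)]] <- ub$gW
    grads[[sprintf("tu%d.b", l)]] <- gb
    gh <- ub$gx
  }
  bb <- drbBackward(gh, cache$bott, P, "bott", U, cfg@gnGroups, s,
                    single = sgl)
  grads[names(bb$grads)] <- bb$grads
  gh <- bb$gx
  for (l in rev(seq_len(L))) {
    tc <- cache$td[[l]]
    ga <- lreluBwd(gh, tc$pre, s)
    gnb <- groupNormBwd(ga, tc$gn, P[[sprintf("td%d.g", l)]])
    grads[[sprintf("td%d.g", l)]] <- gnb$dgamma
    grads[[sprintf("td%d.b", l)]] <- gnb$dbeta
    db <- convdown_bwd_cpp(tc$xin, dim(tc$xin), P[[sprintf("td%d.W", l)]],
                           gnb$gz)
    grads[[sprintf("td%d.W", l)]] <- db$gW
    gblk <- db$gx + gEnc[[l]]
    eb <- drbBackward(gblk, cache$enc[[l]], P, paste0("enc", l), U,
                      cfg@gnGroups, s, single = sgl)
    grads[names(eb$grads)] <- eb$grads
    gh <- eb$gx
  }
  grads
}

#' Run the network on one patch
#'
#' @param network a [DRUNet-class].
#' @param patch 3D array in \[0, 1\] (a normalized image patch) whose every
#'   dimension is divisible by `2^levels`, or a (1, X, Y, Z) array.
#' @return A 3D array of foreground probabilities, strictly inside (0, 1),
#'   with the same spatial shape as the input.
#' @export
drunetForward <- function(network, patch) {
  x <- if (length(dim(patch)) == 3L) array(patch, c(1L, dim(patch)))
       else patch
  p <- netForward(network, x)$p
  array(p, dim(p)[2:4])
}

#' Learned transition down / transition up
#'
#' `transitionDown()` applies a stride-2 2x2x2 convolution followed by group
#' normalization and leaky rectification: every spatial dimension is halved
#' (they must be even) and the channel count doubles. `transitionUp()`
#' applies a stride-2 2x2x2 transposed convolution: spatial dimensions
#' double and channels halve (the channel count must be even). When no
#' weights are supplied, fresh fan-in-initialized ones are drawn.
#'
#' @param features array with dim `(C, X, Y, Z)`.
#' @param W optional weight matrix (`2C x 8C` for down, `8*(C/2) x C` for
#'   up).
#' @param gnGroups,slope normalization groups and leaky slope (down only).
#' @return The transformed feature array.
#' @examples
#' f <- array(rnorm(16 * 8 * 8 * 4), c(16, 8, 8, 4))
#' dim(transitionDown(f))  # 32 x 4 x 4 x 2
#' @export
transitionDown <- function(features, W = NULL, gnGroups = 8L, slope = 0.01) {
  C <- dim(features)[1]
  if (is.null(W)) W <- heInit(2L * C, 8L * C, 8L * C, slope)
  tdForward(features, W, rep(1, 2L * C), rep(0, 2L * C), gnGroups, slope,
            withCache = FALSE)$out
}

#' @rdname transitionDown
#' @export
transitionUp <- function(features, W = NULL, slope = 0.01) {
  C <- dim(features)[1]
  if (C %% 2L != 0L)
    stop("transition up needs an even channel count, got ", C)
  if (is.null(W)) W <- heInit(8L * (C %/% 2L), C, C, slope)
  convup_fwd_cpp(features, dim(features), W)
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the [NetworkConfig-class] together with all
#' parameters, so a loaded network is immediately usable.
#'
#' @param network a [DRUNet-class].
#' @param path file path (RDS).
#' @return `saveCheckpoint()` returns `path` invisibly; `loadCheckpoint()`
#'   returns the [DRUNet-class].
#' @export
saveCheckpoint <- function(network, path) {
  cfg <- network@config
  saveRDS(list(config = list(inChannels = cfg@inChannels,
                             baseWidth = cfg@baseWidth, levels = cfg@levels,
                             unitsPerBlock = cfg@unitsPerBlock,
                             gnGroups = cfg@gnGroups,
                             lreluSlope = cfg@lreluSlope,
                             precision = cfg@precision),
               params = network@params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(networkConfig, ck$config)
  new("DRUNet", config = cfg, params = ck$params)
}
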