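## Synthetic vascular CT phantoms: a recursive bifurcating tree of capsules
## (line segments with radius) rasterized into a ground-truth mask, placed on
## a lung-like noisy background with a soft-tissue blob, all on the pre-clip
## HU scale. Fully parametric and seeded, so every other module can be
## exercised without clinical data.

# sample a bifurcating tree as a list of segments (a, b, radius), in voxel
# coordinates; lengths shrink by `scale` on retries until the tree fits
sampleTree <- function(shape, depth, rootRadius, radiusDecay, scale) {
  segs <- list()
  len0 <- min(shape) * 0.45 * scale
  grow <- function(a, dir, len, radius, gen) {
    b <- a + dir * len
    segs[[length(segs) + 1L]] <<- list(a = a, b = b, radius = radius)
    if (gen >= depth) return()
    for (s in c(-1, 1)) {
      ang <- runif(1, 20, 40) * pi / 180 * s
      twist <- runif(1, -0.4, 0.4)
      # rotate the direction in a randomly tilted plane
      u <- dir / sqrt(sum(dir^2))
      ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      v <- ref - sum(ref * u) * u
      v <- v / sqrt(sum(v^2))
      w <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      vv <- cos(twist) * v + sin(twist) * w
      nd <- cos(ang) * u + sin(ang) * vv
      grow(b, nd, len * 0.75, radius * radiusDecay, gen + 1L)
    }
  }
  root <- c(shape[1] / 2 + runif(1, -2, 2), shape[2] / 2 + runif(1, -2, 2), 1)
  dir0 <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2), 1)
  dir0 <- dir0 / sqrt(sum(dir0^2))
  grow(root, dir0, len0, rootRadius, 0L)
  segs
}

treeFits <- function(segs, shape) {
  pts <- do.call(rbind, lapply(segs, function(s) rbind(s$a, s$b)))
  rad <- max(vapply(segs, `[[`, numeric(1), "radius"))
  all(pts >= 1 - rad * 0.5) &&
    all(sweep(pts, 2, shape, "-") <= rad * 0.5 - 1)
}

# rasterize capsules: voxel centre within `radius` of the segment
rasterizeSegments <- function(segs, shape) {
  mask <- array(0L, shape)
  for (s in segs) {
    r <- s$radius
    lo <- pmax(1L, as.integer(floor(pmin(s$a, s$b) - r - 1)))
    hi <- pmin(shape, as.integer(ceiling(pmax(s$a, s$b) + r + 1)))
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    ab <- s$b - s$a
    denom <- sum(ab^2)
    ap <- sweep(g, 2, s$a, "-")
    t <- if (denom > 0) pmin(1, pmax(0, (ap %*% ab) / denom)) else
      matrix(0, nrow(g), 1)
    cl <- sweep(t %*% rbind(ab), 2, -s$a, "-") # closest point on segment
    d2 <- rowSums((g - cl)^2)
    inside <- g[d2 <= r^2, , drop = FALSE]
    if (nrow(inside))
      mask[inside] <- 1L
  }
  mask
}

#' Generate one synthetic vascular CT phantom
#'
#' Builds a recursive bifurcating tree of capsules (segment radius shrinking
#' by `radiusDecay` per generation), rasterizes it into the ground-truth
#' mask, and composes the image as lung-like background plus an elliptical
#' soft-tissue blob, vessel attenuation inside the mask, and additive
#' Gaussian noise -- all in pre-clip HU. Deterministic given `spec@seed`.
#' If a sampled tree does not fit the grid, it is resampled with shrunken
#' segment lengths (bounded retries).
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `volume` ([CTVolume-class]) and `mask`
#'   ([BinaryMask-class]), sharing spacing, affine and id.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(32L, 32L, 32L), seed = 7L))
#' mean(voxelData(ph$mask))  # small foreground fraction
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  validObject(spec)
  shape <- spec@shape
  withSeed(spec@seed, {
    segs <- list()
    for (tr in seq_len(spec@nTrees)) {
      scale <- 1
      for (try in 1:8) {
        cand <- sampleTree(shape, spec@branchingDepth, spec@rootRadius,
                           spec@radiusDecay, scale)
        if (treeFits(cand, shape)) break
        cand <- NULL
        scale <- scale * 0.8
      }
      if (is.null(cand))
        stop("phantom tree does not fit the volume after 8 shrinking retries")
      segs <- c(segs, cand)
    }
    mask <- rasterizeSegments(segs, shape)

    img <- array(rnorm(prod(shape), spec@lungHU[1], spec@lungHU[2]), shape)
    # soft-tissue blob (mediastinum stand-in) near one lateral face
    cx <- c(shape[1] * 0.15, shape[2] * 0.5, shape[3] * 0.5)
    ax <- shape * c(0.18, 0.3, 0.45)
    idx <- which(array(TRUE, shape))
    co <- arrayInd(idx, shape)
    inblob <- rowSums(sweep(co, 2, cx, "-")^2 / rep(ax^2, each = nrow(co))) <= 1
    img[idx[inblob]] <- rnorm(sum(inblob), spec@softTissueHU[1],
                              spec@softTissueHU[2])
    nf <- sum(mask)
    img[mask == 1L] <- rnorm(nf, spec@vesselHU[1], spec@vesselHU[2])
    img <- img + rnorm(prod(shape), 0, spec@noiseSD)

    id <- sprintf("phantom_%04d", spec@seed)
    list(volume = CTVolume(img, spacing = spec@spacing, id = id),
         mask = BinaryMask(mask, spacing = spec@spacing, id = id))
  })
}

#' Generate a phantom dataset on disk with a manifest
#'
#' Writes `n` image/mask NIfTI pairs (seeds `spec@seed + 0:(n-1)`) plus a
#' JSON manifest consumable by [runCrossValidation()] and the command-line
#' tools. Each manifest entry records `id`, `image_path`, `mask_path` and
#' `split`.
#'
#' @param n number of scans (>= 1).
#' @param spec a [PhantomSpec-class]; per-scan seeds are derived from it.
#' @param outDir output directory, created if needed.
#' @param split split label(s) recycled over scans (default `"train"`).
#' @return The manifest as a data.frame, invisibly; `manifest.json` is
#'   written alongside the volumes.
#' @export
generateDataset <- function(n, spec = phantomSpec(), outDir, split = "train") {
  if (n < 1L) stop("n must be >= 1")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  split <- rep_len(split, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp@seed <- spec@seed + i - 1L
    ph <- generatePhantom(sp)
    ip <- file.path(outDir, sprintf("%s_image.nii.gz", scanId(ph$volume)))
    mp <- file.path(outDir, sprintf("%s_mask.nii.gz", scanId(ph$volume)))
    writeScan(ph$volume, ip)
    writeScan(ph$mask, mp)
    rows[[i]] <- data.frame(id = scanId(ph$volume), image_path = ip,
                            mask_path = mp, split = split[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
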