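## Preprocessing: HU windowing, fixed-bounds min-max normalization, and
## extraction of full-depth in-plane patches with a coverage guarantee.

# run expr with a private RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Clip intensities to a Hounsfield window
#'
#' Clamps every voxel to `[low, high]` HU (default \[-800, 500\], the window
#' that brackets lung parenchyma and contrast-enhanced vessels); in-range
#' voxels are unchanged.
#'
#' @param volume a [CTVolume-class].
#' @param low,high window bounds in HU; `low < high`.
#' @return A [CTVolume-class] with all voxels in `[low, high]`.
#' @examples
#' v <- CTVolume(array(c(-1024, 0, 1000), c(3, 1, 1)))
#' range(voxelData(clipHU(v)))
#' @export
clipHU <- function(volume, low = -800, high = 500) {
  if (low >= high) stop("clip window invalid: low must be < high")
  out <- volume
  out@data <- pmin(pmax(volume@data, low), high)
  out
}

#' Min-max normalize a clipped volume to \[0, 1\]
#'
#' Maps `[low, high]` linearly onto `[0, 1]` using the fixed clip bounds (not
#' per-volume extrema, so the mapping is identical across scanners). The
#' volume must already be clipped.
#'
#' @inheritParams clipHU
#' @return A [CTVolume-class] with values in `[0, 1]`.
#' @export
normalizeIntensity <- function(volume, low = -800, high = 500) {
  if (low >= high) stop("normalization window invalid: low must be < high")
  r <- range(volume@data)
  if (r[1] < low || r[2] > high)
    stop(sprintf("volume has values in [%.4g, %.4g] outside [%g, %g]; clip first",
                 r[1], r[2], low, high))
  out <- volume
  out@data <- (volume@data - low) / (high - low)
  out
}

# Patch corner offsets (0-based, in-plane). Random origins, then if any
# in-plane voxel is left uncovered the trailing origins are replaced by the
# deterministic 3x3 anchor grid at stride (dim - patchXY)/2, which always
# covers the plane.
patchOriginsFor <- function(sourceShape, config) {
  px <- config@patchXY
  mx <- sourceShape[1] - px
  my <- sourceShape[2] - px
  if (mx < 0 || my < 0)
    stop(sprintf("volume in-plane size %d x %d is smaller than patch %d",
                 sourceShape[1], sourceShape[2], px))
  n <- config@patchesPerVolume
  orig <- withSeed(config@seed, cbind(
    floor(runif(n, 0, mx + 1 - 1e-9)),
    floor(runif(n, 0, my + 1 - 1e-9))))
  orig <- matrix(as.integer(orig), ncol = 2L)
  covered <- function(o) {
    cov <- matrix(FALSE, sourceShape[1], sourceShape[2])
    for (r in seq_len(nrow(o)))
      cov[o[r, 1] + seq_len(px), o[r, 2] + seq_len(px)] <- TRUE
    all(cov)
  }
  if (!covered(orig)) {
    anchors <- unique(as.matrix(expand.grid(
      as.integer(round(c(0, mx / 2, mx))),
      as.integer(round(c(0, my / 2, my))))))
    # replace only as many trailing origins as coverage requires, choosing
    # the anchor that covers the most still-uncovered area at each step
    cov <- matrix(FALSE, sourceShape[1], sourceShape[2])
    for (r in seq_len(nrow(orig)))
      cov[orig[r, 1] + seq_len(px), orig[r, 2] + seq_len(px)] <- TRUE
    k <- 0L
    kmax <- min(n, nrow(anchors))
    while (!all(cov) && k < kmax) {
      gain <- vapply(seq_len(nrow(anchors)), function(a) {
        sum(!cov[anchors[a, 1] + seq_len(px), anchors[a, 2] + seq_len(px)])
      }, numeric(1))
      best <- which.max(gain)
      k <- k + 1L
      orig[n - k + 1L, ] <- anchors[best, ]
      cov[anchors[best, 1] + seq_len(px), anchors[best, 2] + seq_len(px)] <- TRUE
      anchors <- anchors[-best, , drop = FALSE]
      # trailing replacement may have dropped coverage contributed by the
      # origin it overwrote; recompute to stay exact
      cov[] <- FALSE
      for (r in seq_len(nrow(orig)))
        cov[orig[r, 1] + seq_len(px), orig[r, 2] + seq_len(px)] <- TRUE
    }
    if (!covered(orig))
      stop(sprintf(
        "cannot guarantee in-plane coverage with %d patches of %d on %d x %d",
        n, px, sourceShape[1], sourceShape[2]))
  }
  dimnames(orig) <- NULL
  orig
}

# cut full-depth patches at the given in-plane origins
cutPatches <- function(data, origins, px, sourceId) {
  shp <- as.integer(dim(data))
  lapply(seq_len(nrow(origins)), function(r) {
    ox <- origins[r, 1]; oy <- origins[r, 2]
    new("PatchRecord",
        patch = data[ox + seq_len(px), oy + seq_len(px), , drop = FALSE],
        origin = as.integer(c(ox, oy, 0L)),
        sourceShape = shp, sourceId = sourceId)
  })
}

#' Extract full-depth in-plane patches from a volume
#'
#' Cuts `patchesPerVolume` patches of `patchXY` x `patchXY` x (full depth)
#' voxels. Origins are drawn uniformly at random (seeded, reproducible) over
#' the valid in-plane offsets; if the random draw leaves any in-plane voxel
#' uncovered, the trailing origins are replaced by a deterministic 3 x 3
#' anchor grid so that the union of patch footprints always covers the
#' plane. This keeps whole-volume reconstruction well defined.
#'
#' @param volume a [CTVolume-class] (or [BinaryMask-class]).
#' @param config a [PreprocessConfig-class]; `patchXY` must not exceed either
#'   in-plane dimension.
#' @return A [PatchSet-class] with exactly `patchesPerVolume` records.
#' @examples
#' v <- CTVolume(array(rnorm(32 * 32 * 8), c(32, 32, 8)))
#' ps <- extractPatches(v, preprocessConfig(patchXY = 16L, seed = 3L))
#' patchOrigins(ps)
#' @export
extractPatches <- function(volume, config = preprocessConfig()) {
  validObject(config)
  shp <- as.integer(dim(volume@data))
  orig <- patchOriginsFor(shp, config)
  new("PatchSet",
      records = cutPatches(volume@data, orig, config@patchXY, volume@id),
      config = config)
}

#' Window, normalize and patch one scan (with its mask, if any)
#'
#' Applies the full preprocessing chain -- clip to `[huLow, huHigh]`,
#' normalize to \[0, 1\], extract patches -- and cuts the mask (when given)
#' at the *same* origins with no interpolation, so image/mask pairs stay
#' voxel-aligned and masks stay binary.
#'
#' @param volume a [CTVolume-class].
#' @param mask an optional [BinaryMask-class], shape-matched to `volume`.
#' @param config a [PreprocessConfig-class].
#' @return A list with elements `image` ([PatchSet-class] of normalized
#'   patches) and `mask` ([PatchSet-class] or `NULL`).
#' @export
preprocessScan <- function(volume, mask = NULL, config = preprocessConfig()) {
  validObject(config)
  if (!is.null(mask) && !all(dim(mask@data) == dim(volume@data)))
    stop(sprintf("mask shape %s does not match volume shape %s",
                 paste(dim(mask@data), collapse = "x"),
                 paste(dim(volume@data), collapse = "x")))
  vol <- normalizeIntensity(clipHU(volume, config@huLow, config@huHigh),
                            config@huLow, config@huHigh)
  shp <- as.integer(dim(vol@data))
  orig <- patchOriginsFor(shp, config)
  img <- new("PatchSet",
             records = cutPatches(vol@data, orig, config@patchXY, vol@id),
             config = config)
  msk <- NULL
  if (!is.null(mask))
    msk <- new("PatchSet",
               records = cutPatches(mask@data, orig, config@patchXY, mask@id),
               config = config)
  list(image = img, mask = msk)
}
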