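## Post-processing: fuse per-patch probability grids back into the source
## frame by averaging overlaps, cut at a probability threshold, and clean
## small components (area-opening analogue) and small background holes
## (area-closing analogue).

#' Reconstruct a source-shaped grid from patch predictions
#'
#' Places every patch back at its recorded origin and sets each voxel to the
#' arithmetic mean of all patch values covering it (overlaps are averaged;
#' probability fusion before thresholding avoids the false-positive bias of
#' max-fusion). Every voxel of the source grid must be covered by at least
#' one patch -- guaranteed by [extractPatches()] -- otherwise an error is
#' raised naming the uncovered count.
#'
#' @param patches a [PatchSet-class] whose records hold (probability) grids.
#' @return A 3D array of the common `sourceShape`.
#' @seealso [binarize()], [removeSmallComponents()]
#' @export
reconstructVolume <- function(patches) {
  stopifnot(is(patches, "PatchSet"))
  recs <- patches@records
  shp <- recs[[1]]@sourceShape
  acc <- array(0, shp)
  cnt <- array(0, shp)
  for (r in recs) {
    if (!all(r@sourceShape == shp))
      stop("patches disagree on source shape; cannot reconstruct")
    ix <- r@origin[1] + seq_len(dim(r@patch)[1])
    iy <- r@origin[2] + seq_len(dim(r@patch)[2])
    iz <- r@origin[3] + seq_len(dim(r@patch)[3])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + r@patch
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  miss <- sum(cnt == 0)
  if (miss > 0)
    stop(sprintf("reconstruction incomplete: %d voxels not covered by any patch",
                 miss))
  acc / cnt
}

#' Threshold a probability grid into a binary mask
#'
#' A voxel becomes foreground iff its probability is strictly greater than
#' `threshold` (ties go to background).
#'
#' @param prob 3D array with values in \[0, 1\].
#' @param threshold cut point in (0, 1), default 0.5.
#' @param spacing,id metadata for the returned mask.
#' @return A [BinaryMask-class].
#' @export
binarize <- function(prob, threshold = 0.5, spacing = c(1, 1, 1), id = "pred") {
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  BinaryMask(array(as.integer(prob > threshold), dim(prob)),
             spacing = spacing, id = id)
}

#' Remove small components and fill small holes
#'
#' Area-opening analogue: connected foreground components (at
#' `config@connectivity`) smaller than `config@minComponentVoxels` are
#' deleted. Area-closing analogue (when `config@fillHoles`): background
#' components smaller than the same bound are filled, using the
#' complementary connectivity (6 for 26-connected foreground and vice
#' versa). Deleting never adds foreground, filling never removes it, and
#' the operation is idempotent.
#'
#' @param mask a [BinaryMask-class] or \{0,1\} array.
#' @param config a [PostprocessConfig-class].
#' @return Same type as `mask`, cleaned.
#' @export
removeSmallComponents <- function(mask, config = postprocessConfig()) {
  validObject(config)
  m <- asMaskArray(mask)
  dm <- dim(m)
  mi <- array(as.integer(m), dm)
  lab <- label_components_cpp(mi, dm, config@connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < config@minComponentVoxels)
    if (length(drop)) mi[lab %in% drop] <- 0L
  }
  if (config@fillHoles) {
    bgconn <- if (config@connectivity == 26L) 6L else 26L
    bg <- 1L - mi
    labb <- label_components_cpp(bg, dm, bgconn)
    if (max(labb) > 0) {
      sizes <- tabulate(labb[labb > 0L])
      fill <- which(sizes < config@minComponentVoxels)
      if (length(fill)) mi[labb %in% fill] <- 1L
    }
  }
  if (is(mask, "BinaryMask")) {
    out <- mask
    out@data <- mi
    out
  } else mi
}
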