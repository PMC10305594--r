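#' Accessors for volume and patch containers
#'
#' `voxelData()` returns the raw 3D array, `voxelSpacing()` the mm spacing,
#' `scanId()` the identifier, `patchRecords()` the list of patches in a
#' [PatchSet-class], `patchOrigins()` their 0-based corner offsets as an
#' n x 3 matrix, and `nPatches()` their number.
#'
#' @param x a [CTVolume-class], [BinaryMask-class] or [PatchSet-class].
#' @return See the individual descriptions.
#' @examples
#' v <- CTVolume(array(0, c(8, 8, 4)), spacing = c(0.7, 0.7, 1))
#' voxelSpacing(v)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))
#' @rdname accessors
#' @export
setGeneric("patchRecords", function(x) standardGeneric("patchRecords"))
#' @rdname accessors
#' @export
setGeneric("patchOrigins", function(x) standardGeneric("patchOrigins"))
#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname accessors
setMethod("voxelData", "CTVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("scanId", "CTVolume", function(x) x@id)
#' @rdname accessors
setMethod("patchRecords", "PatchSet", function(x) x@records)
#' @rdname accessors
setMethod("nPatches", "PatchSet", function(x) length(x@records))
#' @rdname accessors
setMethod("patchOrigins", "PatchSet", function(x) {
  t(vapply(x@records, slot, integer(3), name = "origin"))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s '%s': %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              class(object), object@id, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask '%s': %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              object@id, d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "PatchSet", function(object) {
  r <- object@records[[1]]
  cat(sprintf("PatchSet: %d patches of %s from scan '%s' (%s)\n",
              length(object@records),
              paste(dim(r@patch), collapse = " x "), r@sourceId,
              paste(r@sourceShape, collapse = " x ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s voxels @ %s mm, %d tree(s) depth %d, vessel %g HU on lung %g HU\n",
    paste(object@shape, collapse = "x"),
    paste(object@spacing, collapse = "x"), object@nTrees,
    object@branchingDepth, object@vesselHU[1], object@lungHU[1]))
})
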