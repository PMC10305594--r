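## NIfTI reading and writing (via RNifti). Grids are kept exactly as stored:
## no resampling, no reorientation. Spacing comes from pixdim, the affine
## from the sform/qform; masks are validated to {0,1} on load.

#' Read a CT volume or binary mask from a NIfTI file
#'
#' Reads a NIfTI-1/2 file (`.nii` or `.nii.gz`) into a [CTVolume-class], or,
#' with `mask = TRUE`, into a [BinaryMask-class] after checking that every
#' voxel is exactly 0 or 1. Intensities are held as R doubles regardless of
#' the on-disk dtype; masks are stored as integers.
#'
#' @param path path to an existing NIfTI file.
#' @param mask logical; validate and return a [BinaryMask-class].
#' @param id scan identifier; defaults to the file name without extensions.
#' @return A [CTVolume-class] or [BinaryMask-class] with data, spacing (mm)
#'   and affine populated.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeScan(CTVolume(array(0, c(8, 8, 4)), spacing = c(0.7, 0.7, 1)), f)
#' readScan(f)
#' @seealso [writeScan()]
#' @export
readScan <- function(path, mask = FALSE, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path, internal = FALSE)
  dat <- as.array(img)
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L)
    dat <- array(dat, dim(dat)[1:3])
  if (length(dim(dat)) != 3L)
    stop(sprintf("expected a 3D image, got %d axes in %s",
                 length(dim(dat)), path))
  sp <- as.numeric(RNifti::pixdim(img))[1:3]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (is.null(id))
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  dat <- array(as.double(dat), dim(dat))
  if (mask) {
    bad <- unique(dat[!(dat %in% c(0, 1))])
    if (length(bad))
      stop(sprintf("mask %s contains values outside {0, 1}: %s", path,
                   paste(utils::head(bad, 5L), collapse = ", ")))
    BinaryMask(dat, spacing = sp, affine = aff, id = id)
  } else {
    CTVolume(dat, spacing = sp, affine = aff, id = id)
  }
}

#' Write a volume or mask to a NIfTI file
#'
#' [CTVolume-class] data are written as 32-bit floats, [BinaryMask-class]
#' data as 8-bit unsigned integers. Spacing is stored in pixdim and the
#' affine in the sform (code 2), so a round trip preserves data (bit-exactly
#' for masks, to float precision for HU grids), spacing, and affine.
#'
#' @param volume a [CTVolume-class] or [BinaryMask-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @seealso [readScan()]
#' @export
writeScan <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  validObject(volume)
  dat <- volume@data
  dtype <- if (is(volume, "BinaryMask")) "uint8" else "float"
  attr(dat, "pixdim") <- volume@spacing
  attr(dat, "pixunits") <- c("mm", "s")
  img <- RNifti::asNifti(dat, datatype = dtype)
  img <- RNifti::`sform<-`(img, structure(volume@affine, code = 2L))
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop("cannot write NIfTI to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
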