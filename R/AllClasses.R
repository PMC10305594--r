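## Central S4 containers. Voxel grids are plain 3D numeric arrays in (x, y, z)
## order as stored on disk; spacing is mm per voxel per axis; the affine maps
## 0-based voxel indices to physical mm coordinates (NIfTI convention).

#' CTVolume: a 3D CT grid in Hounsfield units
#'
#' Holds one CT scan: a 3D scalar array of intensities (HU), the voxel
#' spacing in mm along each axis, the voxel-to-world affine, and a scan
#' identifier. No resampling or reorientation is ever applied; the grid is
#' kept exactly as stored.
#'
#' @slot data 3D numeric array of intensities (HU, or \[0,1\] after
#'   normalization).
#' @slot spacing numeric(3), mm per voxel along (x, y, z); all positive.
#' @slot affine 4x4 matrix mapping 0-based voxel indices to mm coordinates.
#' @slot id character scan identifier.
#' @aliases CTVolume
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", affine = "matrix",
                 id = "character"))

#' BinaryMask: a segmentation mask aligned with a CTVolume
#'
#' A 3D grid over \{0, 1\} (background / pulmonary artery) sharing the grid,
#' spacing and affine of its paired [CTVolume].
#'
#' @slot data 3D numeric array with values exactly 0 or 1.
#' @slot spacing,affine,id as in [CTVolume-class].
#' @aliases BinaryMask
#' @export
setClass("BinaryMask", contains = "CTVolume")

.validVolume <- function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, sprintf("grid must have exactly 3 axes, got %d",
                          length(dim(object@data))))
  else if (any(dim(object@data) < 1L))
    msg <- c(msg, "every axis must have length >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive reals (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
}
setValidity("CTVolume", .validVolume)

setValidity("BinaryMask", function(object) {
  bad <- unique(object@data[!(object@data %in% c(0, 1))])
  if (length(bad))
    return(sprintf("mask contains non-binary values: %s",
                   paste(utils::head(bad, 5L), collapse = ", ")))
  TRUE
})

.defaultAffine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

#' Construct a CTVolume
#'
#' @param data 3D numeric array (HU).
#' @param spacing numeric(3) voxel size in mm, default `c(1, 1, 1)`.
#' @param affine optional 4x4 voxel-to-mm matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @param id scan identifier string.
#' @return A validated [CTVolume-class] object.
#' @examples
#' v <- CTVolume(array(0, c(8, 8, 4)), spacing = c(0.7, 0.7, 1))
#' voxelSpacing(v)
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1), affine = NULL, id = "scan") {
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      affine = affine, id = id)
}

#' Construct a BinaryMask
#'
#' @inheritParams CTVolume
#' @param data 3D array with values in \{0, 1\}.
#' @return A validated [BinaryMask-class] object.
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), affine = NULL, id = "mask") {
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  storage.mode(data) <- "integer"
  new("BinaryMask", data = data, spacing = as.numeric(spacing),
      affine = affine, id = id)
}

#' PatchRecord: one sub-volume with its placement in the source grid
#'
#' @slot patch 3D numeric array (patch_xy x patch_xy x source depth).
#' @slot origin integer(3), 0-based voxel offset of the patch corner; extents
#'   are half-open `[origin, origin + dim(patch))`.
#' @slot sourceShape integer(3), shape of the source grid.
#' @slot sourceId character, id of the source scan.
#' @export
setClass("PatchRecord",
  representation(patch = "array", origin = "integer", sourceShape = "integer",
                 sourceId = "character"))

setValidity("PatchRecord", function(object) {
  if (length(dim(object@patch)) != 3L) return("patch must be 3D")
  if (any(object@origin < 0L)) return("origin must be non-negative")
  if (any(object@origin + dim(object@patch) > object@sourceShape))
    return("patch extends beyond the source grid")
  TRUE
})

#' PatchSet: an ordered collection of patches from one scan
#'
#' @slot records list of [PatchRecord-class] objects, all sharing the same
#'   source shape and id.
#' @slot config the [PreprocessConfig-class] that produced the set.
#' @export
setClass("PatchSet",
  representation(records = "list", config = "ANY"))

setValidity("PatchSet", function(object) {
  if (!length(object@records)) return("PatchSet must contain >= 1 record")
  if (!all(vapply(object@records, is, logical(1), class2 = "PatchRecord")))
    return("records must all be PatchRecord objects")
  shp <- vapply(object@records, slot, integer(3), name = "sourceShape")
  if (!all(shp == shp[, 1])) return("records disagree on sourceShape")
  TRUE
})

#' PreprocessConfig: windowing and patch-extraction parameters
#'
#' Defaults implement the published protocol: clip to \[-800, 500\] HU,
#' min-max normalize to \[0, 1\] with the clip bounds as constants, and cut 9
#' full-depth in-plane patches of 256 x 256 voxels per scan.
#'
#' @slot huLow,huHigh clip window in HU (-800, 500).
#' @slot patchesPerVolume number of patches per scan (9).
#' @slot patchXY in-plane patch edge in voxels (256).
#' @slot seed integer seed for the random patch origins.
#' @export
setClass("PreprocessConfig",
  representation(huLow = "numeric", huHigh = "numeric",
                 patchesPerVolume = "integer", patchXY = "integer",
                 seed = "integer"))

setValidity("PreprocessConfig", function(object) {
  if (object@huLow >= object@huHigh) return("huLow must be < huHigh")
  if (object@patchesPerVolume < 1L) return("patchesPerVolume must be >= 1")
  if (object@patchXY < 1L) return("patchXY must be >= 1")
  TRUE
})

#' @rdname PreprocessConfig-class
#' @param huLow,huHigh clip window in HU.
#' @param patchesPerVolume patches extracted per scan.
#' @param patchXY in-plane patch edge (voxels).
#' @param seed integer seed controlling random patch origins.
#' @return A [PreprocessConfig-class] object.
#' @examples
#' preprocessConfig(patchXY = 64L, patchesPerVolume = 4L)
#' @export
preprocessConfig <- function(huLow = -800, huHigh = 500,
                             patchesPerVolume = 9L, patchXY = 256L,
                             seed = 1L) {
  new("PreprocessConfig", huLow = huLow, huHigh = huHigh,
      patchesPerVolume = as.integer(patchesPerVolume),
      patchXY = as.integer(patchXY), seed = as.integer(seed))
}

#' NetworkConfig: DRU-Net architecture hyperparameters
#'
#' The published architecture fixes four encoder and four decoder levels,
#' four conv(3x3x3)/group-norm/LReLU units per dense residual block, and a
#' 1x1x1 sigmoid head; channel width, group count and the leaky slope are
#' left open and configurable here.
#'
#' @slot inChannels input channels (1 for CT).
#' @slot baseWidth channels after the first encoder block; doubles per level.
#' @slot levels encoder/decoder depth (4).
#' @slot unitsPerBlock conv units per dense residual block (4).
#' @slot gnGroups group-normalization groups (8, reduced to divide the
#'   channel count).
#' @slot lreluSlope negative slope of the leaky rectifier (0.01).
#' @slot precision `"single"` (default; the precision a GPU framework would
#'   train in) or `"double"` for the 3x3x3 convolutions. Double precision is
#'   used by the finite-difference gradient validation.
#' @export
setClass("NetworkConfig",
  representation(inChannels = "integer", baseWidth = "integer",
                 levels = "integer", unitsPerBlock = "integer",
                 gnGroups = "integer", lreluSlope = "numeric",
                 precision = "character"))

setValidity("NetworkConfig", function(object) {
  if (object@levels < 1L) return("levels must be >= 1")
  if (object@unitsPerBlock < 1L) return("unitsPerBlock must be >= 1")
  if (object@baseWidth < 1L) return("baseWidth must be >= 1")
  if (object@gnGroups < 1L) return("gnGroups must be >= 1")
  if (!object@precision %in% c("single", "double"))
    return("precision must be 'single' or 'double'")
  TRUE
})

#' @rdname NetworkConfig-class
#' @param inChannels,baseWidth,levels,unitsPerBlock,gnGroups,lreluSlope,precision
#'   see the corresponding slots.
#' @return A [NetworkConfig-class] object.
#' @examples
#' networkConfig(baseWidth = 8L, levels = 2L)
#' @export
networkConfig <- function(inChannels = 1L, baseWidth = 16L, levels = 4L,
                          unitsPerBlock = 4L, gnGroups = 8L,
                          lreluSlope = 0.01, precision = "single") {
  new("NetworkConfig", inChannels = as.integer(inChannels),
      baseWidth = as.integer(baseWidth), levels = as.integer(levels),
      unitsPerBlock = as.integer(unitsPerBlock),
      gnGroups = as.integer(gnGroups), lreluSlope = lreluSlope,
      precision = precision)
}

#' PostprocessConfig: reconstruction and cleanup parameters
#'
#' @slot threshold probability cut for binarization, in (0, 1).
#' @slot minComponentVoxels components smaller than this are removed
#'   (foreground) or filled (background holes).
#' @slot connectivity 6 (faces) or 26 (faces+edges+corners) for foreground
#'   components; holes use the complementary connectivity.
#' @slot fillHoles logical; also fill small background holes.
#' @export
setClass("PostprocessConfig",
  representation(threshold = "numeric", minComponentVoxels = "integer",
                 connectivity = "integer", fillHoles = "logical"))

setValidity("PostprocessConfig", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie strictly inside (0, 1)")
  if (object@minComponentVoxels < 1L) return("minComponentVoxels must be >= 1")
  if (!object@connectivity %in% c(6L, 26L))
    return("connectivity must be 6 or 26")
  TRUE
})

#' @rdname PostprocessConfig-class
#' @param threshold,minComponentVoxels,connectivity,fillHoles see the
#'   corresponding slots.
#' @return A [PostprocessConfig-class] object.
#' @export
postprocessConfig <- function(threshold = 0.5, minComponentVoxels = 64L,
                              connectivity = 26L, fillHoles = TRUE) {
  new("PostprocessConfig", threshold = threshold,
      minComponentVoxels = as.integer(minComponentVoxels),
      connectivity = as.integer(connectivity), fillHoles = fillHoles)
}

#' TrainConfig: optimization and cross-validation parameters
#'
#' Defaults follow the published protocol: Adam with learning rate 1e-4,
#' batch size 1, 200 epochs, 10-fold cross-validation, the DBCE hybrid loss,
#' and in-plane rotation augmentation.
#'
#' @slot learningRate Adam step size (1e-4).
#' @slot batchSize patches per optimizer step (1).
#' @slot epochs training epochs (200).
#' @slot folds cross-validation folds (10).
#' @slot seed integer seed for shuffling, augmentation and initialization.
#' @slot loss one of `"dice"`, `"bce"`, `"dbce"`.
#' @slot augmentMaxAngle maximum in-plane rotation in degrees (15); 0
#'   disables augmentation.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", folds = "integer", seed = "integer",
                 loss = "character", augmentMaxAngle = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@folds < 2L) return("folds must be >= 2")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (!object@loss %in% c("dice", "bce", "dbce"))
    return("loss must be one of dice, bce, dbce")
  if (object@augmentMaxAngle < 0) return("augmentMaxAngle must be >= 0")
  TRUE
})

#' @rdname TrainConfig-class
#' @param learningRate,batchSize,epochs,folds,seed,loss,augmentMaxAngle see
#'   the corresponding slots.
#' @return A [TrainConfig-class] object.
#' @examples
#' trainConfig(epochs = 5L, folds = 2L)
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 1L, epochs = 200L,
                        folds = 10L, seed = 1L, loss = "dbce",
                        augmentMaxAngle = 15) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      folds = as.integer(folds), seed = as.integer(seed), loss = loss,
      augmentMaxAngle = augmentMaxAngle)
}

#' SurfacePointSet: boundary voxel centres in physical coordinates
#'
#' @slot points n x 3 matrix of mm coordinates of boundary voxel centres.
#' @slot spacing numeric(3), the mm spacing the points were scaled by.
#' @export
setClass("SurfacePointSet",
  representation(points = "matrix", spacing = "numeric"))

#' PhantomSpec: parameters of the synthetic vascular CT phantom
#'
#' The generator emulates a contrast-enhanced thoracic CT: a lung-like noisy
#' background, a soft-tissue blob, and a recursive bifurcating tree of
#' capsules at vessel-like attenuation whose rasterization is the ground
#' truth. All intensities are pre-clip HU.
#'
#' @slot shape integer(3) grid size (default 64 x 64 x 32).
#' @slot spacing numeric(3) mm per voxel (default 0.7, 0.7, 1.0, inside the
#'   published 0.50--0.92 mm in-plane range with 1 mm slices).
#' @slot nTrees number of arterial trees (1).
#' @slot branchingDepth bifurcation generations (3).
#' @slot rootRadius trunk radius in voxels (2.5).
#' @slot radiusDecay per-generation radius multiplier in (0, 1) (0.72).
#' @slot vesselHU,lungHU,softTissueHU numeric(2) mean and sd of each tissue
#'   class in HU (300 +/- 30, -850 +/- 40, 40 +/- 20).
#' @slot noiseSD additive Gaussian acquisition noise in HU (15).
#' @slot seed integer seed; the same seed reproduces the phantom bit for bit.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", nTrees = "integer",
                 branchingDepth = "integer", rootRadius = "numeric",
                 radiusDecay = "numeric", vesselHU = "numeric",
                 lungHU = "numeric", softTissueHU = "numeric",
                 noiseSD = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 8L))
    return("shape must be 3 integers >= 8")
  if (object@rootRadius < 1) return("rootRadius must be >= 1 voxel")
  if (object@branchingDepth < 0L) return("branchingDepth must be >= 0")
  if (object@radiusDecay <= 0 || object@radiusDecay >= 1)
    return("radiusDecay must lie in (0, 1)")
  if (any(c(object@vesselHU[2], object@lungHU[2], object@softTissueHU[2],
            object@noiseSD) < 0))
    return("all standard deviations must be >= 0")
  TRUE
})

#' @rdname PhantomSpec-class
#' @param shape,spacing,nTrees,branchingDepth,rootRadius,radiusDecay see the
#'   corresponding slots.
#' @param vesselHU,lungHU,softTissueHU numeric(2): mean, sd in HU.
#' @param noiseSD,seed see the corresponding slots.
#' @return A [PhantomSpec-class] object.
#' @examples
#' phantomSpec(shape = c(32L, 32L, 32L), seed = 7L)
#' @export
phantomSpec <- function(shape = c(64L, 64L, 32L), spacing = c(0.7, 0.7, 1.0),
                        nTrees = 1L, branchingDepth = 3L, rootRadius = 2.5,
                        radiusDecay = 0.72, vesselHU = c(300, 30),
                        lungHU = c(-850, 40), softTissueHU = c(40, 20),
                        noiseSD = 15, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      nTrees = as.integer(nTrees), branchingDepth = as.integer(branchingDepth),
      rootRadius = rootRadius, radiusDecay = radiusDecay,
      vesselHU = vesselHU, lungHU = lungHU, softTissueHU = softTissueHU,
      noiseSD = noiseSD, seed = as.integer(seed))
}
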