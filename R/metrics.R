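## Evaluation metrics: Dice similarity coefficient and the 95th-percentile
## Hausdorff distance in physical millimetres. HD95 takes the 95th
## percentile of each directed surface-distance distribution and then the
## maximum of the two directions (the usual medical-segmentation
## convention); percentiles interpolate linearly between order statistics.

asMaskArray <- function(x) {
  if (is(x, "CTVolume")) x@data else x
}

#' Dice similarity coefficient
#'
#' \deqn{DSC = \frac{2|P \cap G|}{|P| + |G|}}
#'
#' Symmetric overlap between two binary masks. Defined as 1 when both masks
#' are empty and 0 when exactly one is.
#'
#' @param pred,gt shape-matched binary masks ([BinaryMask-class] or plain
#'   \{0,1\} arrays).
#' @return A number in \[0, 1\].
#' @examples
#' a <- array(0, c(4, 4, 1)); b <- a
#' a[1:3, 1, 1] <- 1; a[1, 2:4, 1] <- 1   # |P| = 6
#' b[1:4, 1, 1] <- 1                      # |G| = 4, overlap 3
#' diceCoefficient(a, b)                  # 0.6
#' @seealso [hd95()]
#' @export
diceCoefficient <- function(pred, gt) {
  p <- asMaskArray(pred); g <- asMaskArray(gt)
  if (!identical(dim(p), dim(g)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(p), collapse = "x"), paste(dim(g), collapse = "x")))
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(1)
  2 * sum(p * g) / (np + ng)
}

#' Extract the boundary surface of a mask as physical points
#'
#' A foreground voxel belongs to the surface if at least one of its six
#' face neighbours is background; voxels on the grid edge count as boundary.
#' Voxel centre indices (0-based) are scaled by `spacing` to mm.
#'
#' @param mask a non-empty [BinaryMask-class] or \{0,1\} array.
#' @param spacing numeric(3) mm per voxel; taken from the mask when it is a
#'   [BinaryMask-class].
#' @return A [SurfacePointSet-class] with an n x 3 matrix of mm coordinates.
#' @export
extractSurface <- function(mask, spacing = NULL) {
  m <- asMaskArray(mask)
  if (is.null(spacing))
    spacing <- if (is(mask, "CTVolume")) mask@spacing else c(1, 1, 1)
  if (sum(m) == 0)
    stop("cannot extract a surface from an empty mask")
  d <- dim(m)
  # pad with background so grid-edge voxels count as boundary
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- which(core == 1L & nb < 6L)
  co <- arrayInd(surf, d) - 1L
  pts <- sweep(co * 1.0, 2, spacing, "*")
  new("SurfacePointSet", points = pts, spacing = as.numeric(spacing))
}

#' 95th-percentile Hausdorff distance in millimetres
#'
#' For surfaces \eqn{X} (prediction) and \eqn{Y} (ground truth), computes
#' the directed distance sets \eqn{\{\min_y d(x,y)\}} and
#' \eqn{\{\min_x d(y,x)\}}, takes the `percentile`-th percentile of each
#' (linear interpolation between order statistics), and returns the maximum
#' of the two. At `percentile = 100` this is the classical Hausdorff
#' distance; the 95th percentile trims the influence of a small subset of
#' outlier boundary points. Distances are Euclidean on spacing-scaled voxel
#' centres.
#'
#' @param pred,gt non-empty shape-matched binary masks.
#' @param spacing numeric(3) mm per voxel; taken from `pred` when it is a
#'   [BinaryMask-class].
#' @param percentile percentile in (0, 100\] (default 95).
#' @return Distance in mm (>= 0). Raises an error if either mask is empty
#'   (the metric is undefined there).
#' @examples
#' a <- array(0, c(12, 4, 4)); b <- a
#' a[2, 2, 2] <- 1; b[7, 2, 2] <- 1
#' hd95(a, b, spacing = c(1, 1, 1))  # 5 mm apart
#' @export
hd95 <- function(pred, gt, spacing = NULL, percentile = 95) {
  p <- asMaskArray(pred); g <- asMaskArray(gt)
  if (!identical(dim(p), dim(g)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(p), collapse = "x"), paste(dim(g), collapse = "x")))
  if (is.null(spacing))
    spacing <- if (is(pred, "CTVolume")) pred@spacing else c(1, 1, 1)
  if (sum(p) == 0 || sum(g) == 0)
    stop("HD95 is undefined for an empty mask (no boundary to measure)")
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  sx <- extractSurface(p, spacing)@points
  sy <- extractSurface(g, spacing)@points
  dxy <- directed_min_dists_cpp(sx, sy)
  dyx <- directed_min_dists_cpp(sy, sx)
  max(stats::quantile(dxy, percentile / 100, names = FALSE, type = 7),
      stats::quantile(dyx, percentile / 100, names = FALSE, type = 7))
}

#' Evaluate one prediction against its ground truth
#'
#' @param pred,gt shape-matched [BinaryMask-class] objects.
#' @param scanId identifier for the report row.
#' @return A one-row data.frame (a metrics report) with columns `scan_id`,
#'   `dsc` and `hd95_mm`; `hd95_mm` is `NA` when either mask is empty.
#' @export
evaluateSegmentation <- function(pred, gt, scanId = "scan") {
  d <- diceCoefficient(pred, gt)
  h <- tryCatch(hd95(pred, gt), error = function(e) NA_real_)
  data.frame(scan_id = scanId, dsc = d, hd95_mm = h,
             stringsAsFactors = FALSE)
}
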