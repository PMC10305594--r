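## Training and orchestration: Adam optimization of the DRU-Net under the
## selected loss, seeded in-plane rotation augmentation, whole-scan
## prediction (preprocess -> network -> reconstruct -> cleanup), k-fold
## cross-validation, and the loss-ablation harness.

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Assign scans to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so every scan lands in
#' exactly one fold and fold sizes differ by at most one.
#'
#' @param scanIds character vector of scan identifiers.
#' @param folds number of folds (default 10); must not exceed the number of
#'   scans.
#' @param seed integer seed; the same seed reproduces the split.
#' @return Named integer vector mapping each scan id to a fold in
#'   `1..folds`.
#' @examples
#' table(makeFolds(sprintf("s%02d", 1:100), 10, seed = 1))
#' @export
makeFolds <- function(scanIds, folds = 10L, seed = 1L) {
  n <- length(scanIds)
  if (n < folds)
    stop(sprintf("need at least %d scans for %d folds, got %d", folds,
                 folds, n))
  ord <- withSeed(seed, sample.int(n))
  f <- integer(n)
  f[ord] <- rep_len(seq_len(folds), n)
  names(f) <- scanIds
  f
}

#' Rotate an image/mask patch pair in the axial plane
#'
#' Applies the same in-plane rotation (about the slice centre) to every
#' z-slice of both grids: the image is interpolated bilinearly, the mask by
#' nearest neighbour so it stays strictly binary. The angle is drawn
#' uniformly from `[-maxAngleDeg, maxAngleDeg]` under `seed`, or fixed via
#' `angle`.
#'
#' @param patch 3D image array.
#' @param mask 3D \{0,1\} array, same shape (may be `NULL`).
#' @param maxAngleDeg maximum rotation in degrees.
#' @param seed integer seed for the angle draw.
#' @param angle optional fixed angle in degrees (overrides the draw).
#' @param fill value used outside the source footprint (0 = air after
#'   normalization).
#' @return A list with rotated `patch`, `mask` and the `angle` used.
#' @export
augmentRotate <- function(patch, mask = NULL, maxAngleDeg = 15, seed = 1L,
                          angle = NULL, fill = 0) {
  if (is.null(angle))
    angle <- withSeed(seed, runif(1, -maxAngleDeg, maxAngleDeg))
  if (angle == 0)
    return(list(patch = patch, mask = mask, angle = 0))
  rp <- rotate_slices_cpp(patch, dim(patch), angle, 0L, fill)
  rm <- NULL
  if (!is.null(mask)) {
    rm <- rotate_slices_cpp(mask * 1.0, dim(mask), angle, 1L, 0)
    rm <- array(as.integer(rm), dim(mask))
  }
  list(patch = rp, mask = rm, angle = angle)
}

asPatchArrays <- function(x) {
  if (is(x, "PatchSet")) lapply(x@records, slot, name = "patch")
  else if (is.list(x) && all(vapply(x, is, logical(1), class2 = "PatchSet")))
    unlist(lapply(x, function(ps) lapply(ps@records, slot, name = "patch")),
           recursive = FALSE)
  else x
}

#' Train a DRU-Net on image/mask patches
#'
#' Runs `epochs` passes of shuffled batches (size `batchSize`, gradients
#' averaged within a batch) of forward / loss / backward / Adam step under
#' the configured loss, with optional seeded rotation augmentation. All
#' randomness (initialization, shuffling, augmentation) derives from
#' `trainConfig@seed`, so identical seeds give identical loss curves. A
#' non-finite loss aborts with the epoch, batch and loss value.
#'
#' @param trainImages,trainMasks aligned lists of 3D arrays (or
#'   [PatchSet-class]s / lists of them): normalized image patches and their
#'   binary masks.
#' @param netConfig a [NetworkConfig-class].
#' @param trainConfig a [TrainConfig-class].
#' @param valImages,valMasks optional validation patches; per-epoch
#'   validation DSC is recorded and the best-validation parameters kept.
#' @param network optionally continue training an existing [DRUNet-class].
#' @param stopLoss optional target: training stops early once the epoch-mean
#'   training loss falls below this value.
#' @param verbose print one line per epoch.
#' @return A list: `network` (final), `best` (best-validation network, or
#'   the final one when no validation set is given), and `history` (one row
#'   per epoch: `epoch`, `loss`, `val_dsc`).
#' @export
trainNetwork <- function(trainImages, trainMasks, netConfig = networkConfig(),
                         trainConfig = trainConfig(), valImages = NULL,
                         valMasks = NULL, network = NULL, stopLoss = NULL,
                         verbose = FALSE) {
  validObject(trainConfig)
  imgs <- asPatchArrays(trainImages)
  msks <- asPatchArrays(trainMasks)
  if (length(imgs) == 0L) stop("training set is empty")
  if (length(imgs) != length(msks))
    stop("image and mask patch counts differ")
  vimgs <- if (!is.null(valImages)) asPatchArrays(valImages)
  vmsks <- if (!is.null(valMasks)) asPatchArrays(valMasks)
  withSeed(trainConfig@seed, {
    net <- if (is.null(network)) buildDRUNet(netConfig) else network
    opt <- adamInit(net@params)
    hist <- vector("list", trainConfig@epochs)
    best <- list(dsc = -Inf, params = net@params)
    for (epoch in seq_len(trainConfig@epochs)) {
      ord <- sample.int(length(imgs))
      losses <- numeric(length(ord))
      acc <- NULL
      inBatch <- 0L
      for (bi in seq_along(ord)) {
        i <- ord[bi]
        img <- imgs[[i]]; msk <- msks[[i]]
        if (trainConfig@augmentMaxAngle > 0) {
          aug <- augmentRotate(img, msk, angle = runif(
            1, -trainConfig@augmentMaxAngle, trainConfig@augmentMaxAngle))
          img <- aug$patch; msk <- aug$mask
        }
        x <- array(img, c(1L, dim(img)))
        fw <- netForward(net, x, withCache = TRUE)
        p <- array(fw$p, dim(img))
        lv <- lossWithGrad(trainConfig@loss, p, msk)
        losses[bi] <- lv$value
        if (!is.finite(lv$value))
          stop(sprintf(
            "non-finite %s loss (%g) at epoch %d, batch %d; aborting",
            trainConfig@loss, lv$value, epoch, bi))
        gp <- array(lv$grad, dim(x))
        grads <- netBackward(net, fw$cache, gp)
        acc <- if (is.null(acc)) grads
               else Map(`+`, acc, grads[names(acc)])
        inBatch <- inBatch + 1L
        if (inBatch == trainConfig@batchSize || bi == length(ord)) {
          if (inBatch > 1L) acc <- lapply(acc, `/`, inBatch)
          st <- adamStep(net@params, acc, opt, trainConfig@learningRate)
          net@params <- st$params
          opt <- st$state
          acc <- NULL
          inBatch <- 0L
        }
      }
      vdsc <- NA_real_
      if (!is.null(vimgs) && length(vimgs)) {
        vd <- vapply(seq_along(vimgs), function(i) {
          p <- drunetForward(net, vimgs[[i]])
          diceCoefficient(array(as.integer(p > 0.5), dim(p)), vmsks[[i]])
        }, numeric(1))
        vdsc <- mean(vd)
        if (vdsc > best$dsc) best <- list(dsc = vdsc, params = net@params)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                  val_dsc = vdsc)
      if (verbose)
        message(sprintf("epoch %3d: %s loss %.5f%s", epoch,
                        trainConfig@loss, mean(losses),
                        if (is.na(vdsc)) "" else sprintf(", val DSC %.4f", vdsc)))
      if (!is.null(stopLoss) && mean(losses) < stopLoss) break
    }
    hist <- hist[!vapply(hist, is.null, logical(1))]
    bestNet <- net
    if (is.finite(best$dsc)) bestNet@params <- best$params
    list(network = net, best = bestNet, history = do.call(rbind, hist))
  })
}

# pad spatial dims up to multiples of 2^levels with `fill`, forward, crop
forwardPadded <- function(net, patch, fill = 0) {
  f <- 2L^net@config@levels
  d <- dim(patch)
  target <- as.integer(ceiling(d / f) * f)
  if (all(target == d)) return(drunetForward(net, patch))
  padded <- array(fill, target)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- patch
  p <- drunetForward(net, padded)
  p[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
}

#' Segment a whole CT scan with a trained network
#'
#' Runs the full prediction chain: clip and normalize, extract patches,
#' forward each patch through the network, fuse the per-patch probabilities
#' back into the source frame (averaging overlaps), threshold, and remove
#' small components / fill small holes. Patches whose dimensions are not
#' divisible by `2^levels` are zero-padded for the forward pass and cropped
#' back. The output mask inherits the scan's shape, spacing, affine and id.
#'
#' @param network a trained [DRUNet-class].
#' @param volume a [CTVolume-class] in HU.
#' @param preConfig a [PreprocessConfig-class] (its `patchXY` must fit the
#'   scan).
#' @param postConfig a [PostprocessConfig-class].
#' @return A [BinaryMask-class] aligned with `volume`.
#' @export
predictScan <- function(network, volume, preConfig = preprocessConfig(),
                        postConfig = postprocessConfig()) {
  pp <- preprocessScan(volume, mask = NULL, config = preConfig)
  recs <- lapply(pp$image@records, function(r) {
    r@patch <- forwardPadded(network, r@patch)
    r
  })
  prob <- reconstructVolume(new("PatchSet", records = recs,
                                config = preConfig))
  m <- binarize(prob, postConfig@threshold, spacing = volume@spacing,
                id = volume@id)
  m <- removeSmallComponents(m, postConfig)
  m@affine <- volume@affine
  m
}

#' Load the scans listed in a dataset manifest
#'
#' @param manifest data.frame with columns `id`, `image_path`, `mask_path`
#'   (as written by [generateDataset()]).
#' @return A list of `list(id, volume, mask)` entries.
#' @export
loadManifestScans <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(id = manifest$id[i],
         volume = readScan(manifest$image_path[i], id = manifest$id[i]),
         mask = readScan(manifest$mask_path[i], mask = TRUE,
                         id = manifest$id[i]))
  })
}

collectPatches <- function(scans, preConfig) {
  imgs <- list(); msks <- list()
  for (s in scans) {
    pp <- preprocessScan(s$volume, s$mask, preConfig)
    imgs <- c(imgs, lapply(pp$image@records, slot, name = "patch"))
    msks <- c(msks, lapply(pp$mask@records, slot, name = "patch"))
  }
  list(images = imgs, masks = msks)
}

#' k-fold cross-validation of the full pipeline
#'
#' Splits the non-test scans of `manifest` into `trainConfig@folds` folds
#' ([makeFolds()]); for each fold trains a fresh network on the remaining
#' folds' patches, predicts the held-out scans with [predictScan()], and
#' scores DSC and HD95. Scans whose `split` column (if present) equals
#' `"test"` are excluded, mirroring a held-out test list.
#'
#' @param manifest data.frame with columns `id`, `image_path`, `mask_path`
#'   and optionally `split` (as written by [generateDataset()]), or a list
#'   of `list(id, volume, mask)` entries.
#' @param netConfig,trainConfig,preConfig,postConfig pipeline configuration.
#' @param verbose print per-epoch progress.
#' @return A list: `scans` (one row per held-out scan: `fold`, `scan_id`,
#'   `dsc`, `hd95_mm`), and `folds` (one row per fold plus a final `"mean"`
#'   row of fold averages).
#' @export
runCrossValidation <- function(manifest, netConfig = networkConfig(),
                               trainConfig = trainConfig(),
                               preConfig = preprocessConfig(),
                               postConfig = postprocessConfig(),
                               verbose = FALSE) {
  scans <- if (is.data.frame(manifest)) {
    keep <- if ("split" %in% names(manifest)) manifest$split != "test"
            else rep(TRUE, nrow(manifest))
    loadManifestScans(manifest[keep, , drop = FALSE])
  } else manifest
  ids <- vapply(scans, `[[`, character(1), "id")
  folds <- makeFolds(ids, trainConfig@folds, trainConfig@seed)
  scanRows <- list()
  for (f in sort(unique(folds))) {
    trScans <- scans[folds != f]
    teScans <- scans[folds == f]
    tr <- collectPatches(trScans, preConfig)
    fit <- trainNetwork(tr$images, tr$masks, netConfig, trainConfig,
                        verbose = verbose)
    for (s in teScans) {
      pred <- predictScan(fit$network, s$volume, preConfig, postConfig)
      row <- evaluateSegmentation(pred, s$mask, scanId = s$id)
      row$fold <- f
      scanRows[[length(scanRows) + 1L]] <- row
    }
  }
  perScan <- do.call(rbind, scanRows)
  perFold <- do.call(rbind, lapply(split(perScan, perScan$fold), function(d)
    data.frame(fold = as.character(d$fold[1]), dsc = mean(d$dsc),
               hd95_mm = mean(d$hd95_mm, na.rm = TRUE))))
  perFold <- rbind(perFold,
                   data.frame(fold = "mean", dsc = mean(perFold$dsc),
                              hd95_mm = mean(perFold$hd95_mm)))
  rownames(perFold) <- NULL
  list(scans = perScan, folds = perFold)
}

#' Compare training losses on a fixed train/test split
#'
#' Trains one network per loss in `losses` with otherwise identical
#' configuration, seed and data, evaluates each on the same held-out scans,
#' and returns one comparable row per loss (mean DSC and HD95).
#'
#' @param trainScans,testScans lists of `list(id, volume, mask)` entries (as
#'   from [loadManifestScans()]).
#' @param losses character vector drawn from `"dice"`, `"bce"`, `"dbce"`.
#' @inheritParams runCrossValidation
#' @return data.frame with columns `loss`, `dsc`, `hd95_mm`.
#' @export
ablateLosses <- function(trainScans, testScans,
                         losses = c("dice", "bce", "dbce"),
                         netConfig = networkConfig(),
                         trainConfig = trainConfig(),
                         preConfig = preprocessConfig(),
                         postConfig = postprocessConfig(),
                         verbose = FALSE) {
  tr <- collectPatches(trainScans, preConfig)
  rows <- lapply(losses, function(ls) {
    tc <- trainConfig
    tc@loss <- ls
    fit <- trainNetwork(tr$images, tr$masks, netConfig, tc,
                        verbose = verbose)
    m <- do.call(rbind, lapply(testScans, function(s) {
      pred <- predictScan(fit$network, s$volume, preConfig, postConfig)
      evaluateSegmentation(pred, s$mask, scanId = s$id)
    }))
    data.frame(loss = ls, dsc = mean(m$dsc),
               hd95_mm = mean(m$hd95_mm, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
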