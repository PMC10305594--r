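## Training objectives: Dice loss in the squared-denominator form, voxel-mean
## binary cross-entropy, and their average (the DBCE hybrid). Each loss also
## has an analytic gradient in the prediction, used by the optimizer.

checkLossInputs <- function(p, g) {
  if (!identical(dim(p), dim(g)) || length(p) != length(g))
    stop(sprintf("prediction and ground truth shapes differ: %s vs %s",
                 paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x"),
                 paste(if (is.null(dim(g))) length(g) else dim(g), collapse = "x")))
  if (any(p < 0 | p > 1)) stop("predictions must lie in [0, 1]")
  if (any(!(g %in% c(0, 1)))) stop("ground truth must be binary {0, 1}")
}

#' Dice loss (squared-denominator form)
#'
#' \deqn{L_{Dice} = 1 - \frac{2\sum_i p_i g_i}{\sum_i p_i^2 + \sum_i g_i^2 + \epsilon}}
#'
#' For binary predictions the squares collapse to counts and the loss equals
#' `1 - DSC`. When both prediction and ground truth are identically zero the
#' loss is defined as 0 (perfect agreement on emptiness) rather than letting
#' the smoothing term decide.
#'
#' @param p numeric grid of predicted probabilities in \[0, 1\].
#' @param g numeric grid of ground-truth labels in \{0, 1\}, same shape.
#' @param eps denominator smoothing (1e-6).
#' @return Scalar loss in \[0, 1\].
#' @examples
#' diceLoss(c(0.5, 0.5), c(1, 0))  # 1 - 1/1.5 = 1/3
#' @seealso [bceLoss()], [dbceLoss()], [diceCoefficient()]
#' @export
diceLoss <- function(p, g, eps = 1e-6) {
  checkLossInputs(p, g)
  denom <- sum(p * p) + sum(g * g)
  if (denom == 0) return(0)
  1 - 2 * sum(p * g) / (denom + eps)
}

#' Binary cross-entropy, averaged over voxels
#'
#' \deqn{L_{BCE} = -\frac{1}{N}\sum_i \left[g_i \log p_i + (1-g_i)\log(1-p_i)\right]}
#'
#' Predictions are clamped to `[clamp, 1 - clamp]` before the logarithms.
#'
#' @inheritParams diceLoss
#' @param clamp clamping bound (1e-7).
#' @return Non-negative scalar.
#' @examples
#' bceLoss(rep(0.5, 4), c(1, 0, 1, 0))  # log(2)
#' @export
bceLoss <- function(p, g, clamp = 1e-7) {
  checkLossInputs(p, g)
  pc <- pmin(pmax(p, clamp), 1 - clamp)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

#' DBCE hybrid loss
#'
#' The arithmetic mean of [diceLoss()] and [bceLoss()]: the Dice term
#' handles the foreground/background class imbalance while the cross-entropy
#' term stabilizes the gradients at voxel level.
#'
#' @inheritParams diceLoss
#' @param clamp clamping bound for the cross-entropy term.
#' @return `(bceLoss(p, g) + diceLoss(p, g)) / 2`.
#' @export
dbceLoss <- function(p, g, eps = 1e-6, clamp = 1e-7) {
  (bceLoss(p, g, clamp) + diceLoss(p, g, eps)) / 2
}

# value and d(loss)/dp for the named loss; used by the training loop.
# Gradients are analytic; the clamp zeroes the BCE gradient where active.
lossWithGrad <- function(name, p, g, eps = 1e-6, clamp = 1e-7) {
  checkLossInputs(p, g)
  n <- length(p)
  diceVG <- function() {
    denom <- sum(p * p) + sum(g * g)
    if (denom == 0)
      return(list(value = 0, grad = array(0, dim(p))))
    S <- sum(p * g)
    D <- denom + eps
    list(value = 1 - 2 * S / D,
         grad = -(2 * g * D - 4 * S * p) / D^2)
  }
  bceVG <- function() {
    pc <- pmin(pmax(p, clamp), 1 - clamp)
    gr <- (-(g / pc) + (1 - g) / (1 - pc)) / n
    gr[p < clamp | p > 1 - clamp] <- 0
    list(value = -mean(g * log(pc) + (1 - g) * log(1 - pc)), grad = gr)
  }
  switch(name,
    dice = diceVG(),
    bce = bceVG(),
    dbce = {
      a <- diceVG(); b <- bceVG()
      list(value = (a$value + b$value) / 2, grad = (a$grad + b$grad) / 2)
    },
    stop("unknown loss: ", name))
}
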