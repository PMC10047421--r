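#' Loss configuration
#'
#' The training objective mixes pixel-wise binary cross-entropy with the
#' logarithm of the soft Dice coefficient,
#' `L = (1 - theta) * L_CE - theta * log(Dice)`. `theta = 0` is pure
#' cross-entropy, `theta = 1` pure log-Dice; 0.2 is the default operating
#' point for the heavily imbalanced fracture masks.
#'
#' @param theta Mixing weight in \[0, 1\].
#' @param smooth Small positive constant added to the Dice numerator and
#'   denominator so the coefficient (and its log) stay finite on empty
#'   masks.
#' @param eps Probability clamp applied before logarithms.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(theta = 0.2, smooth = 1, eps = 1e-7) {
  stopifnot(theta >= 0, theta <= 1, smooth > 0, eps > 0, eps < 0.5)
  structure(list(theta = theta, smooth = smooth, eps = eps),
            class = "loss_config")
}

.check_pair <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth))) {
    stop("pred and truth must have identical shapes")
  }
  if (!all(truth %in% c(0, 1))) stop("truth mask must be binary")
}

#' Pixel-wise binary cross-entropy
#'
#' Mean over all pixels of `-[y log(p) + (1 - y) log(1 - p)]`, with
#' probabilities clamped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param pred Probability map in (0, 1).
#' @param truth Binary mask, same shape.
#' @param eps Clamping constant.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(pred, truth, eps = 1e-7) {
  .check_pair(pred, truth)
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Dice coefficient
#'
#' `(2 * sum(y * p) + smooth) / (sum(y) + sum(p) + smooth)`. With a soft
#' (probability) prediction this is the soft Dice used inside the loss;
#' after binarization it is the usual hard overlap Dice. Symmetric in its
#' two arguments.
#'
#' @param pred Prediction in \[0, 1\] (soft or binary).
#' @param truth Binary mask (or second prediction), same shape.
#' @param smooth Smoothing constant (see [loss_config()]).
#' @return Scalar in \[0, 1\].
#' @export
dice_coeff <- function(pred, truth, smooth = 1) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth))) {
    stop("pred and truth must have identical shapes")
  }
  (2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)
}

#' Compound cross-entropy / log-Dice loss
#'
#' `(1 - theta) * L_CE - theta * log(Dice)`; see [loss_config()].
#'
#' @param pred Probability map in (0, 1).
#' @param truth Binary mask, same shape.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
compound_loss <- function(pred, truth, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  .check_pair(pred, truth)
  ce <- cross_entropy_loss(pred, truth, config$eps)
  d <- dice_coeff(pred, truth, config$smooth)
  (1 - config$theta) * ce - config$theta * log(d)
}

#' Analytic gradient of the compound loss with respect to the prediction
#'
#' Exposed for gradient checking; this is the closed form used by the
#' training loop's backward pass. Clamped pixels receive zero
#' cross-entropy gradient.
#'
#' @inheritParams compound_loss
#' @return Array of the same shape as `pred`.
#' @export
compound_loss_grad <- function(pred, truth, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  eps <- config$eps
  m <- length(pred)
  p <- pmin(pmax(pred, eps), 1 - eps)
  live <- (pred > eps) & (pred < 1 - eps)
  dce <- -(truth / p - (1 - truth) / (1 - p)) / m * live
  sy <- sum(truth)
  sp <- sum(pred)
  spy <- sum(pred * truth)
  den <- sp + sy + config$smooth
  dcoef <- (2 * spy + config$smooth) / den
  ddice <- -(2 * truth - dcoef) / (dcoef * den)   # d(-log Dice)/dp
  g <- (1 - config$theta) * dce + config$theta * ddice
  dim(g) <- dim(pred)
  g
}

# Tape node for the compound loss (scalar), with the analytic backward.
ag_compound_loss <- function(tape, pred, truth, config) {
  v <- compound_loss(pred$value, truth, config)
  ag_node(tape, v, list(pred), function(g) {
    list(g * compound_loss_grad(pred$value, truth, config))
  })
}
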