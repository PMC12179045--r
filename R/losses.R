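# Hard-label segmentation losses. All losses consume probabilities (after
# the sigmoid), compare against a binary target of the same shape, and
# return a scalar. Each exported loss has a companion analytic gradient
# with respect to the probabilities, used by the training loop and checked
# against finite differences in the test suite.

LOSS_NAMES <- c("DiceLoss", "CombinedLoss", "TverskyLoss", "ComboLoss",
                "SoftDiceLoss", "DiceBCELoss", "FocalLoss",
                "FocalTverskyLoss", "BCE")

#' Loss configuration
#'
#' @param name one of `"DiceLoss"`, `"CombinedLoss"`, `"TverskyLoss"`,
#'   `"ComboLoss"`, `"SoftDiceLoss"`, `"DiceBCELoss"`, `"FocalLoss"`,
#'   `"FocalTverskyLoss"`, `"BCE"`.
#' @param smooth additive smoothing for overlap losses (default 1).
#' @param tversky_alpha,tversky_beta false-positive / false-negative
#'   weights of the Tversky index (defaults 0.7 / 0.3, weighting
#'   false-negative recovery for thin-vessel emphasis).
#' @param focal_gamma focusing exponent of the focal loss (default 2);
#'   0 reduces it to binary cross-entropy.
#' @param focal_tversky_gamma exponent on the Tversky deficit (default
#'   0.75); 1 reduces it to the Tversky loss.
#' @param combo_weight cross-entropy weight of ComboLoss in `[0, 1]`
#'   (default 0.5).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(name = "DiceBCELoss", smooth = 1,
                        tversky_alpha = 0.7, tversky_beta = 0.3,
                        focal_gamma = 2, focal_tversky_gamma = 0.75,
                        combo_weight = 0.5) {
  if (!name %in% LOSS_NAMES) {
    stop(sprintf("unknown loss '%s'; valid names: %s", name,
                 paste(LOSS_NAMES, collapse = ", ")), call. = FALSE)
  }
  if (smooth < 0 || focal_gamma < 0 || focal_tversky_gamma < 0) {
    stop("smooth and gammas must be >= 0", call. = FALSE)
  }
  if (tversky_alpha + tversky_beta <= 0) {
    stop("tversky_alpha + tversky_beta must be positive", call. = FALSE)
  }
  if (combo_weight < 0 || combo_weight > 1) {
    stop("combo_weight must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, smooth = smooth, tversky_alpha = tversky_alpha,
                 tversky_beta = tversky_beta, focal_gamma = focal_gamma,
                 focal_tversky_gamma = focal_tversky_gamma,
                 combo_weight = combo_weight), class = "loss_config")
}

#' Binary cross-entropy
#'
#' Mean over pixels of `-[y log p + (1 - y) log(1 - p)]` (natural log);
#' probabilities are clamped away from 0 and 1 before the logarithms.
#'
#' @param p probability map in `[0, 1]`.
#' @param y binary target of the same shape.
#' @param eps clamping epsilon for the log terms.
#' @return scalar loss.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  check_same_shape(p, y, "p and y")
  pc <- clamp_probs(p, eps)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

bce_grad <- function(p, y, eps = 1e-7) {
  pc <- clamp_probs(p, eps)
  (-y / pc + (1 - y) / (1 - pc)) / length(p)
}

#' Dice loss
#'
#' `1 - (2 * sum(p y) + smooth) / (sum(p) + sum(y) + smooth)`.
#'
#' @inheritParams bce_loss
#' @param smooth additive smoothing term.
#' @return scalar loss.
#' @export
dice_loss <- function(p, y, smooth = 1) {
  check_same_shape(p, y, "p and y")
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  1 - num / den
}

dice_grad <- function(p, y, smooth = 1) {
  num <- 2 * sum(p * y) + smooth
  den <- sum(p) + sum(y) + smooth
  -(2 * y * den - num) / den^2
}

#' Soft Dice loss (squared-term denominator)
#'
#' `1 - (2 * sum(p y) + smooth) / (sum(p^2) + sum(y^2) + smooth)`.
#'
#' @inheritParams dice_loss
#' @export
soft_dice_loss <- function(p, y, smooth = 1) {
  check_same_shape(p, y, "p and y")
  num <- 2 * sum(p * y) + smooth
  den <- sum(p^2) + sum(y^2) + smooth
  1 - num / den
}

soft_dice_grad <- function(p, y, smooth = 1) {
  num <- 2 * sum(p * y) + smooth
  den <- sum(p^2) + sum(y^2) + smooth
  -(2 * y * den - num * 2 * p) / den^2
}

#' Tversky loss
#'
#' `1 - (TP + smooth) / (TP + alpha FP + beta FN + smooth)` with soft
#' counts `TP = sum(p y)`, `FP = sum(p (1 - y))`, `FN = sum((1 - p) y)`.
#' `alpha = beta = 0.5` recovers the Dice loss.
#'
#' @inheritParams dice_loss
#' @param alpha,beta false-positive and false-negative weights.
#' @export
tversky_loss <- function(p, y, alpha = 0.7, beta = 0.3, smooth = 1) {
  1 - tversky_index(p, y, alpha, beta, smooth)
}

tversky_index <- function(p, y, alpha, beta, smooth) {
  check_same_shape(p, y, "p and y")
  tp <- sum(p * y); fp <- sum(p * (1 - y)); fn <- sum((1 - p) * y)
  (tp + smooth) / (tp + alpha * fp + beta * fn + smooth)
}

tversky_grad <- function(p, y, alpha = 0.7, beta = 0.3, smooth = 1) {
  tp <- sum(p * y); fp <- sum(p * (1 - y)); fn <- sum((1 - p) * y)
  num <- tp + smooth
  den <- tp + alpha * fp + beta * fn + smooth
  dnum <- y
  dden <- y + alpha * (1 - y) - beta * y
  -(dnum * den - num * dden) / den^2
}

#' Focal loss
#'
#' Mean of `-[y (1 - p)^gamma log p + (1 - y) p^gamma log(1 - p)]`, without
#' a class-balancing term so that `gamma = 0` reduces exactly to
#' [bce_loss()].
#'
#' @inheritParams bce_loss
#' @param gamma focusing exponent (>= 0).
#' @export
focal_loss <- function(p, y, gamma = 2, eps = 1e-7) {
  check_same_shape(p, y, "p and y")
  pc <- clamp_probs(p, eps)
  -mean(y * (1 - pc)^gamma * log(pc) + (1 - y) * pc^gamma * log(1 - pc))
}

focal_grad <- function(p, y, gamma = 2, eps = 1e-7) {
  pc <- clamp_probs(p, eps)
  gpos <- (1 - pc)^gamma / pc - gamma * (1 - pc)^(gamma - 1) * log(pc)
  gneg <- gamma * pc^(gamma - 1) * log(1 - pc) - pc^gamma / (1 - pc)
  -(y * gpos + (1 - y) * gneg) / length(p)
}

#' Composite losses
#'
#' `dice_bce_loss` and `combined_loss` are the unit-weight sum of
#' [bce_loss()] and [dice_loss()]; `combo_loss` is the convex combination
#' `w * BCE + (1 - w) * Dice`; `focal_tversky_loss` raises the Tversky
#' deficit to the power `gamma` (`gamma = 1` recovers [tversky_loss()]).
#'
#' @inheritParams dice_loss
#' @export
dice_bce_loss <- function(p, y, smooth = 1) {
  bce_loss(p, y) + dice_loss(p, y, smooth)
}

#' @rdname dice_bce_loss
#' @export
combined_loss <- function(p, y, smooth = 1) {
  bce_loss(p, y) + dice_loss(p, y, smooth)
}

#' @rdname dice_bce_loss
#' @param w cross-entropy weight in `[0, 1]`.
#' @export
combo_loss <- function(p, y, w = 0.5, smooth = 1) {
  w * bce_loss(p, y) + (1 - w) * dice_loss(p, y, smooth)
}

#' @rdname dice_bce_loss
#' @param alpha,beta Tversky false-positive / false-negative weights.
#' @param gamma exponent on the Tversky deficit.
#' @export
focal_tversky_loss <- function(p, y, alpha = 0.7, beta = 0.3, gamma = 0.75,
                               smooth = 1) {
  (1 - tversky_index(p, y, alpha, beta, smooth))^gamma
}

focal_tversky_grad <- function(p, y, alpha = 0.7, beta = 0.3, gamma = 0.75,
                               smooth = 1) {
  deficit <- 1 - tversky_index(p, y, alpha, beta, smooth)
  if (deficit <= 0) return(p * 0)
  gamma * deficit^(gamma - 1) * tversky_grad(p, y, alpha, beta, smooth)
}

#' Build a loss function handle from a configuration
#'
#' @param config a [loss_config()] (or a loss name, using default
#'   hyperparameters).
#' @return list with elements `name`, `fn(p, y)` and `grad(p, y)` (gradient
#'   with respect to the probabilities).
#' @export
make_loss <- function(config = loss_config()) {
  if (is.character(config)) config <- loss_config(config)
  stopifnot(inherits(config, "loss_config"))
  s <- config$smooth
  ta <- config$tversky_alpha; tb <- config$tversky_beta
  fg <- config$focal_gamma; ftg <- config$focal_tversky_gamma
  w <- config$combo_weight
  fns <- switch(config$name,
    BCE = list(fn = function(p, y) bce_loss(p, y),
               grad = function(p, y) bce_grad(p, y)),
    DiceLoss = list(fn = function(p, y) dice_loss(p, y, s),
                    grad = function(p, y) dice_grad(p, y, s)),
    SoftDiceLoss = list(fn = function(p, y) soft_dice_loss(p, y, s),
                        grad = function(p, y) soft_dice_grad(p, y, s)),
    TverskyLoss = list(fn = function(p, y) tversky_loss(p, y, ta, tb, s),
                       grad = function(p, y) tversky_grad(p, y, ta, tb, s)),
    FocalLoss = list(fn = function(p, y) focal_loss(p, y, fg),
                     grad = function(p, y) focal_grad(p, y, fg)),
    DiceBCELoss = list(fn = function(p, y) dice_bce_loss(p, y, s),
                       grad = function(p, y) bce_grad(p, y) + dice_grad(p, y, s)),
    CombinedLoss = list(fn = function(p, y) combined_loss(p, y, s),
                        grad = function(p, y) bce_grad(p, y) + dice_grad(p, y, s)),
    ComboLoss = list(fn = function(p, y) combo_loss(p, y, w, s),
                     grad = function(p, y) w * bce_grad(p, y) + (1 - w) * dice_grad(p, y, s)),
    FocalTverskyLoss = list(fn = function(p, y) focal_tversky_loss(p, y, ta, tb, ftg, s),
                            grad = function(p, y) focal_tversky_grad(p, y, ta, tb, ftg, s))
  )
  c(list(name = config$name, config = config), fns)
}
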