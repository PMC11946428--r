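# Segmentation losses: soft Dice, Tversky, binary cross-entropy, the two
# hybrid combinations, and the deep-supervision total with its periodically
# decaying auxiliary weight. All region losses use soft counts
# (Intersection = sum(p*y), FP = sum(p*(1-y)), FN = sum((1-p)*y)) so they
# are differentiable in the predicted probabilities; gradient helpers are
# provided for the native training loop and are expressed with respect to
# the pre-sigmoid logits.

#' Loss configuration
#'
#' @param epsilon smoothing term added to loss denominators.
#' @param tversky_alpha,tversky_beta false-positive and false-negative
#'   weights of the Tversky loss.
#' @param lambda mixing weight of the hybrid losses (weight of the
#'   cross-entropy term).
#' @param ds_alpha0 initial deep-supervision auxiliary weight.
#' @param ds_decay multiplicative decay factor applied once per period.
#' @param ds_decay_period_epochs decay period in epochs.
#' @return object of class \code{loss_config}.
#' @export
loss_config <- function(epsilon = 1e-5, tversky_alpha = 0.3,
                        tversky_beta = 0.7, lambda = 0.5, ds_alpha0 = 0.4,
                        ds_decay = 0.8, ds_decay_period_epochs = 30L) {
  stopifnot(epsilon > 0, lambda >= 0, lambda <= 1,
            tversky_alpha >= 0, tversky_beta >= 0,
            tversky_alpha + tversky_beta <= 2,
            ds_decay > 0, ds_decay <= 1)
  structure(list(epsilon = epsilon, tversky_alpha = tversky_alpha,
                 tversky_beta = tversky_beta, lambda = lambda,
                 ds_alpha0 = ds_alpha0, ds_decay = ds_decay,
                 ds_decay_period_epochs = as.integer(ds_decay_period_epochs)),
            class = "loss_config")
}

check_pair <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)) &&
      length(predicted) != length(target))
    stop("predicted and target shapes differ")
  if (any(predicted < 0 | predicted > 1))
    stop("predicted values must be probabilities in [0, 1]")
  if (any(target != 0 & target != 1))
    stop("target values must be binary")
  invisible(NULL)
}

#' Soft Dice loss
#'
#' \code{1 - 2 * Intersection / (Union + epsilon)} with
#' \code{Union = sum(predicted) + sum(target)}.
#'
#' @param predicted array of probabilities in \[0, 1\].
#' @param target binary array of the same shape.
#' @param epsilon smoothing term.
#' @return scalar loss.
#' @export
dice_loss <- function(predicted, target, epsilon = 1e-5) {
  check_pair(predicted, target)
  inter <- sum(predicted * target)
  union <- sum(predicted) + sum(target)
  1 - 2 * inter / (union + epsilon)
}

#' Tversky loss
#'
#' \code{1 - I / (I + alpha * FP + beta * FN + epsilon)} with soft
#' false-positive and false-negative counts.
#'
#' @inheritParams dice_loss
#' @param alpha false-positive weight.
#' @param beta false-negative weight.
#' @return scalar loss.
#' @export
tversky_loss <- function(predicted, target, alpha = 0.3, beta = 0.7,
                         epsilon = 1e-5) {
  check_pair(predicted, target)
  inter <- sum(predicted * target)
  fp <- sum(predicted * (1 - target))
  fn <- sum((1 - predicted) * target)
  1 - inter / (inter + alpha * fp + beta * fn + epsilon)
}

#' Binary cross-entropy loss
#'
#' Mean over voxels of \code{-[y log(p) + (1-y) log(1-p)]}, with
#' probabilities clamped to \[clamp, 1-clamp\].
#'
#' @inheritParams dice_loss
#' @param clamp numerical floor for the probabilities inside the logs.
#' @return scalar loss.
#' @export
bce_loss <- function(predicted, target, clamp = 1e-7) {
  check_pair(predicted, target)
  p <- pmin(pmax(predicted, clamp), 1 - clamp)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Hybrid losses
#'
#' \code{hybrid1 = (1 - lambda) * DiceLoss + lambda * BCELoss};
#' \code{hybrid2} uses the Tversky loss in place of the Dice loss.
#'
#' @inheritParams dice_loss
#' @param lambda mixing weight in \[0, 1\].
#' @param config a [loss_config()] supplying the component parameters.
#' @return scalar loss.
#' @export
hybrid1_loss <- function(predicted, target, lambda = 0.5,
                         config = loss_config()) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  (1 - lambda) * dice_loss(predicted, target, config$epsilon) +
    lambda * bce_loss(predicted, target)
}

#' @rdname hybrid1_loss
#' @export
hybrid2_loss <- function(predicted, target, lambda = 0.5,
                         config = loss_config()) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  (1 - lambda) * tversky_loss(predicted, target, config$tversky_alpha,
                              config$tversky_beta, config$epsilon) +
    lambda * bce_loss(predicted, target)
}

#' Resolve a loss function by name
#'
#' @param name one of \code{"dice"}, \code{"tversky"}, \code{"bce"},
#'   \code{"hybrid1"}, \code{"hybrid2"}.
#' @param config a [loss_config()].
#' @return function of \code{(predicted, target)} returning a scalar loss.
#' @export
get_loss <- function(name = c("hybrid1", "dice", "tversky", "bce", "hybrid2"),
                     config = loss_config()) {
  name <- match.arg(name)
  switch(name,
         dice = function(p, y) dice_loss(p, y, config$epsilon),
         tversky = function(p, y) tversky_loss(p, y, config$tversky_alpha,
                                               config$tversky_beta,
                                               config$epsilon),
         bce = function(p, y) bce_loss(p, y),
         hybrid1 = function(p, y) hybrid1_loss(p, y, config$lambda, config),
         hybrid2 = function(p, y) hybrid2_loss(p, y, config$lambda, config))
}

#' Deep-supervision total loss
#'
#' \code{total = loss3 + ds_alpha * (loss0 + loss1 + loss2)} where
#' \code{loss3} is the full-resolution output's loss and \code{loss0..2}
#' are the auxiliary (coarser-head) losses.
#'
#' @param losses numeric vector of exactly 4 finite values
#'   \code{(loss0, loss1, loss2, loss3)}.
#' @param ds_alpha auxiliary weight.
#' @return scalar total loss.
#' @export
deep_supervision_total <- function(losses, ds_alpha = 0.4) {
  if (length(losses) != 4L)
    stop("deep supervision expects exactly 4 losses, got ", length(losses))
  if (!all(is.finite(losses))) stop("non-finite loss values")
  losses[4] + ds_alpha * sum(losses[1:3])
}

#' Decay the deep-supervision weight
#'
#' Applied once per configured period: \code{ds_alpha * decay}.
#'
#' @param ds_alpha current weight (>= 0).
#' @param decay multiplicative factor.
#' @return decayed weight.
#' @export
decay_ds_alpha <- function(ds_alpha, decay = 0.8) {
  stopifnot(ds_alpha >= 0)
  ds_alpha * decay
}

# ---- logit-space gradients for the training loop ----------------------------
# Each returns list(loss, dlogit) where dlogit = dLoss/dz for p = sigmoid(z).

sigmoid <- function(z) 1 / (1 + exp(-z))

loss_grad_logits <- function(name, z, y, config = loss_config()) {
  p <- sigmoid(z)
  dp_dz <- p * (1 - p)
  eps <- config$epsilon
  n <- length(y)
  comp <- function(nm) {
    switch(nm,
      dice = {
        inter <- sum(p * y); union <- sum(p) + sum(y)
        loss <- 1 - 2 * inter / (union + eps)
        dldp <- -2 * (y * (union + eps) - inter) / (union + eps)^2
        list(loss = loss, dz = dldp * dp_dz)
      },
      tversky = {
        a <- config$tversky_alpha; b <- config$tversky_beta
        inter <- sum(p * y); fp <- sum(p * (1 - y)); fn <- sum((1 - p) * y)
        den <- inter + a * fp + b * fn + eps
        loss <- 1 - inter / den
        dldp <- -(y * den - inter * (y + a * (1 - y) - b * y)) / den^2
        list(loss = loss, dz = dldp * dp_dz)
      },
      bce = {
        pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
        list(loss = loss, dz = (p - y) / n)
      })
  }
  lam <- config$lambda
  switch(name,
    dice = comp("dice"),
    tversky = comp("tversky"),
    bce = comp("bce"),
    hybrid1 = {
      d <- comp("dice"); b <- comp("bce")
      list(loss = (1 - lam) * d$loss + lam * b$loss,
           dz = (1 - lam) * d$dz + lam * b$dz)
    },
    hybrid2 = {
      t <- comp("tversky"); b <- comp("bce")
      list(loss = (1 - lam) * t$loss + lam * b$loss,
           dz = (1 - lam) * t$dz + lam * b$dz)
    },
    stop("unknown loss: ", name))
}
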