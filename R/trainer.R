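# Native training loop: Adam with step-decayed learning rate, deterministic
# 3:1 splits, foreground-oversampled patch sampling and the decaying
# deep-supervision schedule.

#' Training configuration
#'
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative decay applied every \code{lr_period}
#'   epochs (20\% reduction by default).
#' @param lr_period decay period in epochs.
#' @param epochs number of epochs.
#' @param steps_per_epoch optimization steps (one patch each) per epoch.
#' @param patch_size training patch dims (divisible by 8).
#' @param oversample_fraction fraction of patches centered on a foreground
#'   voxel; the rest are uniform.
#' @param loss_name one of \code{"dice"}, \code{"tversky"}, \code{"bce"},
#'   \code{"hybrid1"}, \code{"hybrid2"}.
#' @param split_ratio train fraction of the train/validation split.
#' @param seed RNG seed covering split, patch sampling and weight updates.
#' @param loss a [loss_config()] (also carries the deep-supervision
#'   schedule).
#' @return object of class \code{train_config}.
#' @export
train_config <- function(lr0 = 1e-4, lr_decay = 0.8, lr_period = 30L,
                         epochs = 10L, steps_per_epoch = 30L,
                         patch_size = c(64L, 64L, 32L),
                         oversample_fraction = 0.5,
                         loss_name = "hybrid1", split_ratio = 0.75,
                         seed = 1L, loss = loss_config()) {
  stopifnot(lr0 > 0, lr_decay > 0, lr_decay <= 1,
            oversample_fraction >= 0, oversample_fraction <= 1)
  structure(list(lr0 = lr0, lr_decay = lr_decay,
                 lr_period = as.integer(lr_period),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 patch_size = as.integer(patch_size),
                 oversample_fraction = oversample_fraction,
                 loss_name = loss_name, split_ratio = split_ratio,
                 seed = as.integer(seed), loss = loss),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: \code{lr0 * decay^floor(epoch / period)}.
#'
#' @param epoch 0-based epoch index.
#' @param lr0 initial learning rate.
#' @param decay per-period factor.
#' @param period epochs per step.
#' @return scalar learning rate.
#' @export
lr_at_epoch <- function(epoch, lr0 = 1e-4, decay = 0.8, period = 30L) {
  stopifnot(all(epoch >= 0))
  lr0 * decay^floor(epoch / period)
}

#' Deterministic train/validation split
#'
#' @param case_ids vector of at least 4 case identifiers.
#' @param ratio train fraction (3:1 split by default).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return list with \code{train} and \code{val} id vectors (disjoint,
#'   exhaustive; \code{|train| = round(ratio * n)}).
#' @export
make_splits <- function(case_ids, ratio = 0.75, seed = 1L) {
  n <- length(case_ids)
  if (n < 4L) stop("need at least 4 cases to split, got ", n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample(n)
  n_train <- as.integer(round(ratio * n))
  list(train = case_ids[sort(perm[seq_len(n_train)])],
       val = case_ids[sort(perm[n_train + seq_len(n - n_train)])])
}

# one training patch: returns list(input, target) arrays of patch_size;
# draws from the current RNG stream
sample_patch <- function(volume, target, patch_size, oversample_fraction) {
  d <- dim(volume)
  ps <- pmin(patch_size, d)
  # volumes smaller than the patch use their natural size, padded only to
  # the backbone's divisibility requirement, not up to the full patch
  full <- pmin(patch_size, as.integer(ceiling(d / 8) * 8L))
  fg <- NULL
  use_fg <- stats::runif(1) < oversample_fraction
  if (use_fg) {
    fg <- which(target != 0)
    if (length(fg) == 0L) {
      warning("no foreground voxels; falling back to uniform sampling")
      use_fg <- FALSE
    }
  }
  if (use_fg) {
    v <- fg[sample.int(length(fg), 1L)]
    ctr <- arrayInd(v, d)[1, ]
    lo <- pmin(pmax(ctr - ps %/% 2L, 1L), d - ps + 1L)
  } else {
    lo <- vapply(seq_len(3), function(ax) {
      sample.int(d[ax] - ps[ax] + 1L, 1L)
    }, 1L)
  }
  ix <- lo[1] + seq_len(ps[1]) - 1L
  iy <- lo[2] + seq_len(ps[2]) - 1L
  iz <- lo[3] + seq_len(ps[3]) - 1L
  inp <- volume[ix, iy, iz, drop = FALSE]
  tgt <- target[ix, iy, iz, drop = FALSE]
  if (any(ps < full)) {
    inp <- pad_to(inp, full)$arr
    tgt <- pad_to(tgt, full)$arr
  }
  list(input = inp, target = tgt, origin = lo - 1L)
}

adam_step <- function(net, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in collect_layers(net)) {
    for (p in l$params) {
      g <- l[[paste0("g_", p)]]
      if (is.null(g)) next
      mkey <- paste0("adam_m_", p)
      vkey <- paste0("adam_v_", p)
      if (is.null(l[[mkey]])) {
        l[[mkey]] <- g * 0
        l[[vkey]] <- g * 0
      }
      l[[mkey]] <- beta1 * l[[mkey]] + (1 - beta1) * g
      l[[vkey]] <- beta2 * l[[vkey]] + (1 - beta2) * g^2
      mhat <- l[[mkey]] / (1 - beta1^t)
      vhat <- l[[vkey]] / (1 - beta2^t)
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  zero_grads(net)
  invisible(NULL)
}

# crop a case to the (true) liver ROI for stage-2 training
crop_case_to_roi <- function(vol, lab, margin = 10L) {
  liver <- lab >= 1L
  if (!any(liver)) return(list(volume = vol, label = lab))
  roi <- liver_roi(liver, margin)
  ix <- (roi$lo[1] + 1L):roi$hi[1]
  iy <- (roi$lo[2] + 1L):roi$hi[2]
  iz <- (roi$lo[3] + 1L):roi$hi[3]
  list(volume = vol[ix, iy, iz, drop = FALSE],
       label = lab[ix, iy, iz, drop = FALSE])
}

#' Train one cascade stage
#'
#' Runs the native Adam loop on preprocessed cases. For the liver stage the
#' target is label >= 1; for the tumor stage the target is label == 2 and
#' every case is first cropped to its ground-truth liver ROI, so stage-2
#' training only ever consumes voxels inside the liver region. One patch is
#' drawn per step (foreground-oversampled), the four deep-supervision
#' losses are combined as \code{loss3 + ds_alpha * (loss0+loss1+loss2)},
#' and \code{ds_alpha} decays by its configured factor once per period.
#'
#' @param net a \code{segnet} (updated in place).
#' @param cases list of preprocessed cases, each
#'   \code{list(volume = 3D array, label = 3D integer array)}.
#' @param config a [train_config()].
#' @param stage \code{"liver"} or \code{"tumor"}.
#' @param val_cases optional held-out cases; per-epoch validation Dice of
#'   the thresholded full-volume prediction is recorded and the weights of
#'   the best validation epoch are kept.
#' @param verbose print per-epoch summaries.
#' @return list with \code{history} (per-step data.frame: epoch, step,
#'   total loss, ds_alpha, lr), \code{val} (per-epoch data.frame or NULL)
#'   and \code{net}.
#' @export
train_stage <- function(net, cases, config = train_config(),
                        stage = c("liver", "tumor"), val_cases = NULL,
                        verbose = FALSE) {
  stage <- match.arg(stage)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  target_of <- function(lab)
    if (stage == "liver") (lab >= 1L) * 1 else (lab == 2L) * 1
  prep <- function(cs) {
    if (stage == "tumor") cs <- lapply(cs, function(ca)
      crop_case_to_roi(ca$volume, ca$label))
    lapply(cs, function(ca) list(volume = ca$volume,
                                 target = target_of(ca$label)))
  }
  tr <- prep(cases)
  vl <- if (!is.null(val_cases)) prep(val_cases)
  ds_alpha <- config$loss$ds_alpha0
  hist <- list()
  val_hist <- list()
  best <- list(dice = -Inf, weights = NULL)
  t_adam <- 0L
  for (epoch in seq_len(config$epochs) - 1L) {
    if (epoch > 0L && epoch %% config$loss$ds_decay_period_epochs == 0L)
      ds_alpha <- decay_ds_alpha(ds_alpha, config$loss$ds_decay)
    lr <- lr_at_epoch(epoch, config$lr0, config$lr_decay, config$lr_period)
    for (step in seq_len(config$steps_per_epoch)) {
      ca <- tr[[sample.int(length(tr), 1L)]]
      pa <- sample_patch(ca$volume, ca$target, config$patch_size,
                         config$oversample_fraction)
      zs <- network_forward(net, pa$input, training = TRUE)
      y <- pa$target
      dim(y) <- c(dim(y), 1L)
      losses <- numeric(4)
      dlogits <- vector("list", 4)
      for (k in 1:4) {
        lg <- loss_grad_logits(config$loss_name, zs[[k]], y, config$loss)
        losses[k] <- lg$loss
        wk <- if (k == 4) 1 else ds_alpha
        dlogits[[k]] <- array(wk * lg$dz, dim = dim(zs[[k]]))
      }
      total <- deep_supervision_total(losses, ds_alpha)
      if (!is.finite(total))
        stop("training diverged: non-finite loss at epoch ", epoch,
             " step ", step)
      network_backward(net, dlogits)
      t_adam <- t_adam + 1L
      adam_step(net, lr, t_adam)
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = epoch, step = step, total_loss = total,
        ds_alpha = ds_alpha, lr = lr)
    }
    if (!is.null(vl)) {
      vd <- mean(vapply(vl, function(ca) {
        prob <- sliding_window_predict(net, ca$volume, config$patch_size,
                                       overlap = 0)
        dice_score(prob >= 0.5, ca$target != 0)
      }, 0))
      val_hist[[length(val_hist) + 1L]] <-
        data.frame(epoch = epoch, val_dice = vd)
      if (vd > best$dice)
        best <- list(dice = vd, weights = get_weights(net))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val dice %.4f", epoch,
                        hist[[length(hist)]]$total_loss, vd))
    } else if (verbose) {
      message(sprintf("epoch %d: loss %.4f", epoch,
                      hist[[length(hist)]]$total_loss))
    }
  }
  if (!is.null(vl) && !is.null(best$weights)) set_weights(net, best$weights)
  list(history = do.call(rbind, hist),
       val = if (length(val_hist)) do.call(rbind, val_hist),
       net = net)
}

#' Extract / restore network weights
#'
#' Weights (and normalization running statistics) as a flat list, in stable
#' traversal order; useful for checkpointing with \code{saveRDS()}.
#'
#' @param net a \code{segnet}.
#' @return list of parameter arrays.
#' @export
get_weights <- function(net) {
  lapply(collect_layers(net), function(l) {
    out <- lapply(l$params, function(p) l[[p]])
    names(out) <- l$params
    if (!is.null(l$run_mean)) {
      out$run_mean <- l$run_mean
      out$run_var <- l$run_var
    }
    out
  })
}

#' @rdname get_weights
#' @param weights a list produced by [get_weights()] on an identically
#'   configured network.
#' @export
set_weights <- function(net, weights) {
  layers <- collect_layers(net)
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(weights[[i]])) l[[nm]] <- weights[[i]][[nm]]
  }
  invisible(net)
}
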