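# Structural re-parameterization: fold normalization statistics into
# convolution weights and merge parallel linear branches into one kernel,
# so each trained re-parameterizable unit collapses to a single convolution
# for deployment. Merging is exact linear algebra; only accumulation
# round-off distinguishes the two forms.

#' Branch weights for re-parameterization
#'
#' A dense convolution branch: an odd-sized kernel, a per-output-channel
#' bias, and optionally the normalization statistics still to be folded in.
#'
#' @param kernel 5-d array \code{(kx, ky, kz, Cin, Cout)} with odd spatial
#'   sizes.
#' @param bias numeric vector of length \code{Cout} (defaults to zeros).
#' @param norm_stats optional list with elements \code{mean}, \code{var},
#'   \code{scale}, \code{shift}, \code{eps} (each per output channel except
#'   the scalar \code{eps}).
#' @return object of class \code{branch_weights}.
#' @export
branch_weights <- function(kernel, bias = NULL, norm_stats = NULL) {
  stopifnot(length(dim(kernel)) == 5)
  if (any(dim(kernel)[1:3] %% 2 == 0))
    stop("branch kernels must have odd spatial sizes")
  cout <- dim(kernel)[5]
  if (is.null(bias)) bias <- numeric(cout)
  stopifnot(length(bias) == cout)
  if (!is.null(norm_stats)) {
    stopifnot(all(c("mean", "var", "scale", "shift", "eps") %in%
                    names(norm_stats)))
    if (any(norm_stats$var + norm_stats$eps <= 0))
      stop("normalization variance + eps must be positive")
  }
  structure(list(kernel = kernel, bias = bias, norm_stats = norm_stats),
            class = "branch_weights")
}

#' Identity branch as a centered delta kernel
#'
#' @param channels number of (equal) input and output channels.
#' @param size odd spatial kernel size of the merge target.
#' @return a [branch_weights()] whose convolution is the identity map.
#' @export
identity_branch <- function(channels, size = 1L) {
  k <- array(0, dim = c(size, size, size, channels, channels))
  ctr <- (size + 1L) / 2L
  for (c in seq_len(channels)) k[ctr, ctr, ctr, c, c] <- 1
  branch_weights(k)
}

#' Fold normalization statistics into a convolution branch
#'
#' Rescales the kernel by \code{scale / sqrt(var + eps)} per output channel
#' and absorbs \code{mean} and \code{shift} into the bias, so the folded
#' branch computes exactly what convolution followed by the (frozen)
#' normalization computed.
#'
#' @param branch a [branch_weights()] with \code{norm_stats} present.
#' @return a norm-free [branch_weights()].
#' @export
fuse_norm <- function(branch) {
  ns <- branch$norm_stats
  if (is.null(ns)) stop("branch has no normalization statistics to fold")
  f <- ns$scale / sqrt(ns$var + ns$eps)
  k <- branch$kernel
  cout <- dim(k)[5]
  for (c in seq_len(cout)) k[, , , , c] <- k[, , , , c] * f[c]
  b <- (branch$bias - ns$mean) * f + ns$shift
  branch_weights(k, b)
}

pad_kernel <- function(kernel, target) {
  d <- dim(kernel)
  if (any(d[1:3] > target)) stop("branch kernel larger than merge target")
  out <- array(0, dim = c(target, target, target, d[4], d[5]))
  off <- (target - d[1:3]) / 2
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3]), , ] <-
    kernel
  out
}

#' Merge parallel convolution branches into one kernel
#'
#' Zero-pads every branch kernel to the (odd) target size, centered, and
#' sums kernels and biases. Convolution with the merged kernel equals the
#' sum of the branch convolutions exactly, up to floating-point round-off.
#'
#' @param branches list of norm-free [branch_weights()] with identical
#'   channel counts.
#' @param target_size odd integer target kernel size.
#' @return a single merged [branch_weights()].
#' @export
merge_branches <- function(branches, target_size = 3L) {
  if (target_size %% 2 == 0) stop("merge target size must be odd")
  stopifnot(length(branches) >= 1)
  for (b in branches) {
    if (!is.null(b$norm_stats))
      stop("fold normalization (fuse_norm) before merging")
  }
  ch <- dim(branches[[1]]$kernel)[4:5]
  k <- array(0, dim = c(target_size, target_size, target_size, ch[1], ch[2]))
  bias <- numeric(ch[2])
  for (b in branches) {
    if (!all(dim(b$kernel)[4:5] == ch))
      stop("branch channel counts are incompatible")
    k <- k + pad_kernel(b$kernel, target_size)
    bias <- bias + b$bias
  }
  branch_weights(k, bias)
}

rep_units_of <- function(net) {
  Filter(function(m) inherits(m, "lv_repunit"), all_modules(net))
}

all_modules <- function(obj) {
  if (inherits(obj, "lv_module"))
    return(c(list(obj), all_modules(obj$children)))
  if (is.list(obj)) return(do.call(c, lapply(obj, all_modules)))
  list()
}

fuse_repunit <- function(unit) {
  ch <- unit$children
  h <- unit$h
  branches <- lapply(ch$b3, function(cv) branch_weights(cv$w))
  w1 <- array(ch$b1$w, dim = c(1, 1, 1, h, h))
  branches <- c(branches, list(branch_weights(w1), identity_branch(h)))
  merged <- merge_branches(branches, 3L)
  bn <- ch$bn
  fuse_norm(branch_weights(merged$kernel, merged$bias,
                           norm_stats = list(mean = bn$run_mean,
                                             var = bn$run_var,
                                             scale = bn$gamma,
                                             shift = bn$beta,
                                             eps = bn$eps)))
}

#' Convert a trained network to its deployed form
#'
#' Replaces every re-parameterizable unit by its single fused 3x3x3
#' convolution (parallel branches merged, post-sum normalization folded).
#' Deployed outputs match evaluation-mode outputs of the training form up
#' to floating-point accumulation, and the parameter count strictly
#' decreases for every multi-branch unit.
#'
#' @param net a \code{segnet} (modified in place and returned).
#' @return the deployed network.
#' @export
convert_to_deploy <- function(net) {
  if (is_deployed(net)) {
    warning("network is already deployed; nothing to convert")
    return(net)
  }
  for (unit in rep_units_of(net)) {
    fused <- fuse_repunit(unit)
    conv <- layer_conv3d(unit$h, unit$h, k = 3, bias = TRUE)
    conv$w <- fused$kernel
    conv$b <- fused$bias
    unit$deploy <- conv
    unit$children <- list(deploy = conv, act = unit$children$act)
  }
  net$config$deploy <- TRUE
  net
}

#' Is the network in deployed form?
#'
#' @param net a \code{segnet}.
#' @return logical.
#' @export
is_deployed <- function(net) isTRUE(net$config$deploy)
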