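# Composite network blocks: plain convolution units, the re-parameterizable
# residual block (ELANRes) and the slice-wise multi-scale convolutional
# attention block (MSCA).

# ---- conv -> BN -> ReLU -----------------------------------------------------

block_cvunit <- function(cin, cout, k = 3, stride = 1) {
  new_module("cvunit",
             children = list(conv = layer_conv3d(cin, cout, k, stride),
                             bn = layer_bn(cout), act = layer_relu()))
}

lv_forward.lv_cvunit <- function(layer, x, training = FALSE) {
  ch <- layer$children
  lv_forward(ch$act, lv_forward(ch$bn, lv_forward(ch$conv, x, training),
                                training), training)
}

lv_backward.lv_cvunit <- function(layer, dy) {
  ch <- layer$children
  lv_backward(ch$conv, lv_backward(ch$bn, lv_backward(ch$act, dy)))
}

# ---- trilinear x2 upsampling followed by conv -> BN -> ReLU -----------------

block_up <- function(cin, cout) {
  new_module("upblock",
             children = list(up = layer_up2(),
                             unit = block_cvunit(cin, cout)))
}

lv_forward.lv_upblock <- function(layer, x, training = FALSE) {
  ch <- layer$children
  lv_forward(ch$unit, lv_forward(ch$up, x, training), training)
}

lv_backward.lv_upblock <- function(layer, dy) {
  ch <- layer$children
  lv_backward(ch$up, lv_backward(ch$unit, dy))
}

# ---- re-parameterizable unit ------------------------------------------------
# training form: sum of `branches` parallel 3x3x3 convs, one 1x1x1 conv and
# the identity, followed by one BN and ReLU; deploy form: a single fused
# 3x3x3 conv with bias, then ReLU.

block_repunit <- function(h, branches = 2) {
  convs <- lapply(seq_len(branches), function(i) layer_conv3d(h, h, 3))
  new_module("repunit",
             children = list(b3 = convs, b1 = layer_pconv3d(h, h),
                             bn = layer_bn(h), act = layer_relu()),
             h = h, deploy = NULL)
}

lv_forward.lv_repunit <- function(layer, x, training = FALSE) {
  if (!is.null(layer$deploy))
    return(lv_forward(layer$children$act,
                      lv_forward(layer$deploy, x, training), training))
  ch <- layer$children
  s <- lv_forward(ch$b1, x, training) + x
  for (cv in ch$b3) s <- s + lv_forward(cv, x, training)
  lv_forward(ch$act, lv_forward(ch$bn, s, training), training)
}

lv_backward.lv_repunit <- function(layer, dy) {
  ch <- layer$children
  ds <- lv_backward(ch$bn, lv_backward(ch$act, dy))
  dx <- lv_backward(ch$b1, ds) + ds
  for (cv in ch$b3) dx <- dx + lv_backward(cv, ds)
  dx
}

# ---- ELANRes block ----------------------------------------------------------
# 1x1 stem widens the input to split + hidden channels; the hidden path runs
# through `units` sequential re-parameterizable units whose outputs are all
# concatenated with the untouched split and fused by a 1x1 conv; a projected
# residual of the block input is added before the output activation.

block_elanres <- function(cin, cout, hidden, split, units = 3, branches = 2) {
  reps <- lapply(seq_len(units), function(i) block_repunit(hidden, branches))
  new_module("elanres",
             children = list(
               stem = layer_pconv3d(cin, split + hidden),
               bn_stem = layer_bn(split + hidden), act_stem = layer_relu(),
               reps = reps,
               fusion = layer_pconv3d(split + units * hidden, cout),
               bn_fus = layer_bn(cout),
               proj = layer_pconv3d(cin, cout), bn_proj = layer_bn(cout),
               act_out = layer_relu()),
             hidden = hidden, split = split, units = units)
}

lv_forward.lv_elanres <- function(layer, x, training = FALSE) {
  ch <- layer$children
  t <- lv_forward(ch$act_stem,
                  lv_forward(ch$bn_stem, lv_forward(ch$stem, x, training),
                             training), training)
  sp <- split_channels(t, layer$split)
  q <- sp$second
  cat <- sp$first
  for (rp in ch$reps) {
    q <- lv_forward(rp, q, training)
    cat <- cat_channels(cat, q)
  }
  f <- lv_forward(ch$bn_fus, lv_forward(ch$fusion, cat, training), training)
  p <- lv_forward(ch$bn_proj, lv_forward(ch$proj, x, training), training)
  lv_forward(ch$act_out, f + p, training)
}

lv_backward.lv_elanres <- function(layer, dy) {
  ch <- layer$children
  u <- layer$units
  h <- layer$hidden
  s <- layer$split
  d <- lv_backward(ch$act_out, dy)
  dxp <- lv_backward(ch$proj, lv_backward(ch$bn_proj, d))
  dcat <- lv_backward(ch$fusion, lv_backward(ch$bn_fus, d))
  dpass <- dcat[, , , seq_len(s), drop = FALSE]
  dq <- NULL
  for (j in rev(seq_len(u))) {
    dslice <- dcat[, , , s + (j - 1L) * h + seq_len(h), drop = FALSE]
    dq <- if (is.null(dq)) dslice else dq + dslice
    dq <- lv_backward(ch$reps[[j]], dq)
  }
  dt <- cat_channels(dpass, dq)
  dxs <- lv_backward(ch$stem,
                     lv_backward(ch$bn_stem, lv_backward(ch$act_stem, dt)))
  dxs + dxp
}

# ---- MSCA block -------------------------------------------------------------
# Slice-folded 2D attention: normalize, sum depthwise multi-scale kernels
# (5x5 and the 1x7/7x1, 1x11/11x1, 1x21/21x1 strip pairs), mix channels with
# a 1x1 conv, multiply the result with the normalized features, add the block
# input, then a residual MLP (1x1 up, depthwise 3x3, GELU, 1x1 down).

block_msca <- function(c, mlp_hidden) {
  new_module("msca",
             children = list(
               norm1 = layer_inorm2d(c),
               dw5 = layer_dwconv2d(c, 5, 5),
               dw7a = layer_dwconv2d(c, 1, 7), dw7b = layer_dwconv2d(c, 7, 1),
               dw11a = layer_dwconv2d(c, 1, 11), dw11b = layer_dwconv2d(c, 11, 1),
               dw21a = layer_dwconv2d(c, 1, 21), dw21b = layer_dwconv2d(c, 21, 1),
               mix = layer_pconv2d(c, c),
               norm2 = layer_inorm2d(c),
               mlp_up = layer_pconv2d(c, mlp_hidden),
               mlp_dw = layer_dwconv2d(mlp_hidden, 3, 3),
               mlp_act = layer_gelu(),
               mlp_down = layer_pconv2d(mlp_hidden, c)),
             c = c, mlp_hidden = mlp_hidden)
}

lv_forward.lv_msca <- function(layer, x, training = FALSE) {
  ch <- layer$children
  x2 <- volume_to_slices(x)
  u <- lv_forward(ch$norm1, x2, training)
  a <- lv_forward(ch$dw5, u, training) +
    lv_forward(ch$dw7b, lv_forward(ch$dw7a, u, training), training) +
    lv_forward(ch$dw11b, lv_forward(ch$dw11a, u, training), training) +
    lv_forward(ch$dw21b, lv_forward(ch$dw21a, u, training), training)
  g <- lv_forward(ch$mix, a, training)
  r <- x2 + g * u
  w <- lv_forward(ch$norm2, r, training)
  t <- lv_forward(ch$mlp_down,
         lv_forward(ch$mlp_act,
           lv_forward(ch$mlp_dw,
             lv_forward(ch$mlp_up, w, training), training), training), training)
  if (training) {
    layer$u <- u
    layer$g <- g
  }
  slices_to_volume(r + t)
}

lv_backward.lv_msca <- function(layer, dy) {
  ch <- layer$children
  dout <- volume_to_slices(dy)
  dw_ <- lv_backward(ch$mlp_up,
           lv_backward(ch$mlp_dw,
             lv_backward(ch$mlp_act, lv_backward(ch$mlp_down, dout))))
  dr <- dout + lv_backward(ch$norm2, dw_)
  dx2 <- dr
  dg <- dr * layer$u
  du <- dr * layer$g
  da <- lv_backward(ch$mix, dg)
  du <- du + lv_backward(ch$dw5, da) +
    lv_backward(ch$dw7a, lv_backward(ch$dw7b, da)) +
    lv_backward(ch$dw11a, lv_backward(ch$dw11b, da)) +
    lv_backward(ch$dw21a, lv_backward(ch$dw21b, da))
  dx2 <- dx2 + lv_backward(ch$norm1, du)
  layer$u <- NULL
  layer$g <- NULL
  slices_to_volume(dx2)
}

#' Fold the slice axis of a volumetric feature map into the batch axis
#'
#' The multi-scale attention block runs 2D convolutions slice by slice. This
#' transform reorders a volumetric feature map of dim \code{(X, Y, Z, C)}
#' into a stack of 2D maps of dim \code{(X, Y, C, Z)} whose last axis acts
#' as the batch of slices; [slices_to_volume()] is its exact inverse.
#'
#' @param x 4-dimensional array, dim \code{(X, Y, Z, C)}.
#' @return 4-dimensional array, dim \code{(X, Y, C, Z)}.
#' @export
volume_to_slices <- function(x) {
  stopifnot(length(dim(x)) == 4)
  aperm(x, c(1, 2, 4, 3))
}

#' Inverse of [volume_to_slices()]
#'
#' @param x 4-dimensional array, dim \code{(X, Y, C, Z)}.
#' @return 4-dimensional array, dim \code{(X, Y, Z, C)}.
#' @export
slices_to_volume <- function(x) {
  stopifnot(length(dim(x)) == 4)
  aperm(x, c(1, 2, 4, 3))
}

# ---- deep supervision head --------------------------------------------------
# 1x1x1 conv to one logit channel, trilinearly upsampled to full resolution

block_head <- function(c, level) {
  conv <- layer_pconv3d(c, 1, bias = TRUE)
  # bias the initial foreground probability low (~0.12): segmentation
  # foregrounds are rare, and a prior-matched head keeps early
  # cross-entropy gradients from flattening the foreground sigmoid
  conv$b[] <- -2
  new_module("head", children = list(conv = conv), level = level)
}

lv_forward.lv_head <- function(layer, x, training = FALSE) {
  z <- lv_forward(layer$children$conv, x, training)
  if (layer$level > 0) {
    layer$zdim <- dim(z)
    z <- .cpp_trilinear_resize(z, as.integer(c(dim(z)[1:3] * 2L^layer$level, 1L)))
  }
  z
}

lv_backward.lv_head <- function(layer, dy) {
  if (layer$level > 0)
    dy <- .cpp_trilinear_resize_bwd(dy, as.integer(layer$zdim))
  lv_backward(layer$children$conv, dy)
}
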