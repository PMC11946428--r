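# Minimal dense-array neural layer engine.
#
# Feature maps are plain double arrays, dim (X, Y, Z, C) for volumetric
# layers and (X, Y, C, M) for slice-folded 2D layers (M = slices). Each
# layer is an environment holding weights, Adam state, cached activations
# and gradient accumulators; lv_forward()/lv_backward() dispatch on class.
# Backward passes are hand-derived and verified against finite differences
# in the test suite.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$type <- type
  class(e) <- c(paste0("lv_", type), "lv_layer")
  e
}

#' @keywords internal
lv_forward <- function(layer, x, training = FALSE) UseMethod("lv_forward")

#' @keywords internal
lv_backward <- function(layer, dy) UseMethod("lv_backward")

he_init <- function(dims, fan_in, gain = 2) {
  array(stats::rnorm(prod(dims), sd = sqrt(gain / fan_in)), dim = dims)
}

acc_grad <- function(layer, name, g) {
  cur <- layer[[name]]
  layer[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# ---- 3D convolution (cubic kernel, zero pad (k-1)/2, optional stride) -------

layer_conv3d <- function(cin, cout, k = 3, stride = 1, bias = FALSE) {
  w <- he_init(c(k, k, k, cin, cout), fan_in = k^3 * cin)
  new_layer("conv3d", w = w, b = if (bias) numeric(cout) else NULL,
            stride = as.integer(stride), params = c("w", if (bias) "b"))
}

lv_forward.lv_conv3d <- function(layer, x, training = FALSE) {
  y <- .cpp_conv3d_fwd(x, layer$w, layer$stride)
  if (!is.null(layer$b))
    y <- y + rep(layer$b, each = prod(dim(y)[1:3]))
  if (training) layer$x <- x
  y
}

lv_backward.lv_conv3d <- function(layer, dy) {
  g <- .cpp_conv3d_bwd(layer$x, layer$w, dy, layer$stride)
  acc_grad(layer, "g_w", g$dw)
  if (!is.null(layer$b))
    acc_grad(layer, "g_b", colSums(matrix(dy, ncol = dim(dy)[4])))
  layer$x <- NULL
  g$dx
}

# ---- pointwise (1x1x1) convolution as channel mixing ------------------------

layer_pconv3d <- function(cin, cout, bias = FALSE) {
  new_layer("pconv3d", w = he_init(c(cin, cout), fan_in = cin),
            b = if (bias) numeric(cout) else NULL,
            params = c("w", if (bias) "b"))
}

lv_forward.lv_pconv3d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  ym <- xm %*% layer$w
  if (!is.null(layer$b)) ym <- sweep(ym, 2, layer$b, "+")
  if (training) layer$xm <- xm
  array(ym, dim = c(d[1:3], ncol(layer$w)))
}

lv_backward.lv_pconv3d <- function(layer, dy) {
  d <- dim(dy)
  dym <- matrix(dy, ncol = d[4])
  acc_grad(layer, "g_w", crossprod(layer$xm, dym))
  if (!is.null(layer$b)) acc_grad(layer, "g_b", colSums(dym))
  dx <- dym %*% t(layer$w)
  layer$xm <- NULL
  array(dx, dim = c(d[1:3], nrow(layer$w)))
}

# ---- batch normalization over all voxels per channel ------------------------

layer_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  new_layer("bn", gamma = rep(1, c), beta = numeric(c),
            run_mean = numeric(c), run_var = rep(1, c),
            eps = eps, momentum = momentum, params = c("gamma", "beta"))
}

lv_forward.lv_bn <- function(layer, x, training = FALSE) {
  r <- .cpp_bn_fwd(x, layer$gamma, layer$beta, layer$run_mean,
                   layer$run_var, layer$eps, training)
  if (training) {
    mu <- r$mean
    v <- 1 / r$istd^2 - layer$eps
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
    layer$xh <- r$xh
    layer$istd <- r$istd
  }
  r$y
}

lv_backward.lv_bn <- function(layer, dy) {
  g <- .cpp_bn_bwd(dy, layer$xh, layer$gamma, layer$istd)
  acc_grad(layer, "g_gamma", g$dgamma)
  acc_grad(layer, "g_beta", g$dbeta)
  layer$xh <- NULL; layer$istd <- NULL
  g$dx
}

# ---- instance normalization on slice-folded maps ----------------------------
# stats per (channel, slice) over the in-plane voxels; affine per channel

layer_inorm2d <- function(c, eps = 1e-5) {
  new_layer("inorm2d", gamma = rep(1, c), beta = numeric(c), eps = eps,
            params = c("gamma", "beta"))
}

lv_forward.lv_inorm2d <- function(layer, x, training = FALSE) {
  d <- dim(x)                                  # (X, Y, C, M)
  n <- d[1] * d[2]
  xm <- matrix(x, nrow = n)                    # n x (C*M)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(v + layer$eps)
  xh <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
  gam <- rep(layer$gamma, times = d[4])
  ym <- sweep(sweep(xh, 2, gam, "*"), 2, rep(layer$beta, times = d[4]), "+")
  if (training) {
    layer$xh <- xh
    layer$istd <- istd
    layer$d <- d
  }
  array(ym, dim = d)
}

lv_backward.lv_inorm2d <- function(layer, dy) {
  d <- layer$d
  n <- d[1] * d[2]
  dym <- matrix(dy, nrow = n)
  xh <- layer$xh
  gs <- colSums(dym * xh)
  bs <- colSums(dym)
  acc_grad(layer, "g_gamma", rowSums(matrix(gs, nrow = d[3])))
  acc_grad(layer, "g_beta", rowSums(matrix(bs, nrow = d[3])))
  gam <- rep(layer$gamma, times = d[4])
  t1 <- sweep(dym, 2, bs / n, "-")
  t2 <- sweep(xh, 2, gs / n, "*")
  dx <- sweep(t1 - t2, 2, gam * layer$istd, "*")
  layer$xh <- NULL; layer$istd <- NULL
  array(dx, dim = d)
}

# ---- activations ------------------------------------------------------------

layer_relu <- function() new_layer("relu", params = character())

lv_forward.lv_relu <- function(layer, x, training = FALSE) {
  y <- .cpp_relu_fwd(x)
  if (training) layer$y <- y
  y
}

lv_backward.lv_relu <- function(layer, dy) {
  dx <- .cpp_relu_bwd(dy, layer$y)
  layer$y <- NULL
  dx
}

layer_gelu <- function() new_layer("gelu", params = character())

lv_forward.lv_gelu <- function(layer, x, training = FALSE) {
  if (training) layer$x <- x
  x * stats::pnorm(x)
}

lv_backward.lv_gelu <- function(layer, dy) {
  x <- layer$x
  dx <- dy * (stats::pnorm(x) + x * stats::dnorm(x))
  layer$x <- NULL
  dx
}

# ---- depthwise 2D convolution (kx x ky, stride 1, same padding) -------------

layer_dwconv2d <- function(c, kx, ky) {
  w <- he_init(c(kx, ky, c), fan_in = kx * ky)
  new_layer("dwconv2d", w = w, b = numeric(c), params = c("w", "b"))
}

lv_forward.lv_dwconv2d <- function(layer, x, training = FALSE) {
  if (training) layer$x <- x
  .cpp_dwconv2d_fwd(x, layer$w, layer$b)
}

lv_backward.lv_dwconv2d <- function(layer, dy) {
  g <- .cpp_dwconv2d_bwd(layer$x, layer$w, dy)
  acc_grad(layer, "g_w", g$dw)
  acc_grad(layer, "g_b", g$db)
  layer$x <- NULL
  g$dx
}

# ---- pointwise 2D convolution on slice-folded maps --------------------------

layer_pconv2d <- function(cin, cout, bias = TRUE) {
  new_layer("pconv2d", w = he_init(c(cin, cout), fan_in = cin),
            b = if (bias) numeric(cout) else NULL,
            params = c("w", if (bias) "b"))
}

lv_forward.lv_pconv2d <- function(layer, x, training = FALSE) {
  d <- dim(x)                                  # (X, Y, C, M)
  xp <- aperm(x, c(1, 2, 4, 3))
  xm <- matrix(xp, ncol = d[3])
  ym <- xm %*% layer$w
  if (!is.null(layer$b)) ym <- sweep(ym, 2, layer$b, "+")
  if (training) {
    layer$xm <- xm
    layer$d <- d
  }
  aperm(array(ym, dim = c(d[1], d[2], d[4], ncol(layer$w))), c(1, 2, 4, 3))
}

lv_backward.lv_pconv2d <- function(layer, dy) {
  d <- layer$d
  dyp <- aperm(dy, c(1, 2, 4, 3))
  dym <- matrix(dyp, ncol = dim(dy)[3])
  acc_grad(layer, "g_w", crossprod(layer$xm, dym))
  if (!is.null(layer$b)) acc_grad(layer, "g_b", colSums(dym))
  dxm <- dym %*% t(layer$w)
  layer$xm <- NULL
  aperm(array(dxm, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

# ---- trilinear x2 upsampling ------------------------------------------------

layer_up2 <- function() new_layer("up2", params = character())

lv_forward.lv_up2 <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (training) layer$indim <- d
  .cpp_trilinear_resize(x, as.integer(c(d[1:3] * 2L, d[4])))
}

lv_backward.lv_up2 <- function(layer, dy) {
  dx <- .cpp_trilinear_resize_bwd(dy, as.integer(layer$indim))
  layer$indim <- NULL
  dx
}

# ---- utilities over layer collections ---------------------------------------

# composite modules: environments holding child layers under $children plus
# forward/backward caches; they dispatch through the same generics
new_module <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$type <- type
  class(e) <- c(paste0("lv_", type), "lv_module")
  e
}

# depth-first walk collecting every lv_layer environment in a nested structure
collect_layers <- function(obj) {
  if (inherits(obj, "lv_module")) return(collect_layers(obj$children))
  if (inherits(obj, "lv_layer")) return(list(obj))
  if (is.list(obj)) return(do.call(c, lapply(obj, collect_layers)))
  list()
}

n_params <- function(obj) {
  sum(vapply(collect_layers(obj), function(l) {
    sum(vapply(l$params, function(p) length(l[[p]]), 0))
  }, 0))
}

zero_grads <- function(obj) {
  for (l in collect_layers(obj))
    for (p in l$params) l[[paste0("g_", p)]] <- NULL
  invisible(NULL)
}

# channel concatenation / split helpers (last dim)
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

split_channels <- function(x, n_first) {
  d <- dim(x)
  list(first = x[, , , seq_len(n_first), drop = FALSE],
       second = x[, , , n_first + seq_len(d[4] - n_first), drop = FALSE])
}
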