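# Layer-engine correctness: compiled convolution kernels against brute
# force, hand-derived backward passes against finite differences, and the
# resize operators' adjoint identity.

conv3_bruteforce <- function(x, w, stride = 1) {
  d <- dim(x)
  k <- dim(w)[1]
  p <- (k - 1) / 2
  od <- c(floor((d[1:3] + 2 * p - k) / stride) + 1, dim(w)[5])
  out <- array(0, dim = od)
  for (co in seq_len(od[4])) for (zo in seq_len(od[3]))
    for (yo in seq_len(od[2])) for (xo in seq_len(od[1])) {
      acc <- 0
      for (ci in seq_len(d[4])) for (l in 1:k) for (j in 1:k) for (i in 1:k) {
        xx <- (xo - 1) * stride + i - p
        yy <- (yo - 1) * stride + j - p
        zz <- (zo - 1) * stride + l - p
        if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
            zz >= 1 && zz <= d[3])
          acc <- acc + x[xx, yy, zz, ci] * w[i, j, l, ci, co]
      }
      out[xo, yo, zo, co] <- acc
    }
  out
}

test_that("compiled 3D convolution matches brute force at strides 1 and 2", {
  set.seed(10)
  x <- array(rnorm(7 * 6 * 5 * 3), dim = c(7, 6, 5, 3))
  w <- array(rnorm(27 * 3 * 2), dim = c(3, 3, 3, 3, 2))
  expect_lt(max(abs(.cpp_conv3d_fwd(x, w, 1L) - conv3_bruteforce(x, w, 1))),
            1e-5)
  expect_lt(max(abs(.cpp_conv3d_fwd(x, w, 2L) - conv3_bruteforce(x, w, 2))),
            1e-10)
})

test_that("layer backward passes match finite differences", {
  set.seed(11)
  d <- c(6, 6, 4, 3)
  x0 <- array(rnorm(prod(d)), dim = d)
  # h and tolerance sized for the engine's single-precision convolutions
  h <- 1e-4
  layers <- list(conv = layer_conv3d(3, 2, bias = TRUE),
                 pconv = layer_pconv3d(3, 2, bias = TRUE),
                 bn = layer_bn(3),
                 relu = layer_relu(),
                 gelu = layer_gelu(),
                 up = layer_up2())
  for (nm in names(layers)) {
    layer <- layers[[nm]]
    f <- function(xin) lv_forward(layer, xin, training = TRUE)
    y0 <- f(x0)
    dy <- array(rnorm(length(y0)), dim = dim(y0))
    loss0 <- sum(y0 * dy)
    zero_grads(layer)
    invisible(f(x0))                   # refresh caches for backward
    dx <- lv_backward(layer, dy)
    gsnap <- lapply(layer$params, function(p) layer[[paste0("g_", p)]])
    names(gsnap) <- layer$params
    # input gradient
    i <- 17
    xp <- x0
    xp[i] <- xp[i] + h
    fd <- (sum(f(xp) * dy) - loss0) / h
    lv_backward(layer, dy)             # clear caches
    expect_lt(abs(fd - dx[i]) / max(1e-4, abs(fd)), 5e-3,
              label = paste(nm, "dx"))
    # weight gradients
    for (p in layer$params) {
      g <- gsnap[[p]]
      j <- 1L
      old <- layer[[p]][j]
      layer[[p]][j] <- old + h
      fdw <- (sum(f(x0) * dy) - loss0) / h
      lv_backward(layer, dy)
      layer[[p]][j] <- old
      expect_lt(abs(fdw - g[j]) / max(1e-4, abs(fdw)), 5e-3,
                label = paste(nm, p))
    }
  }
})

test_that("slice-folded 2D layers agree with finite differences", {
  set.seed(12)
  d <- c(6, 5, 3, 4)                        # (X, Y, C, M)
  x <- array(rnorm(prod(d)), dim = d)
  for (layer in list(layer_dwconv2d(3, 1, 7), layer_dwconv2d(3, 5, 5),
                     layer_pconv2d(3, 2), layer_inorm2d(3))) {
    y <- lv_forward(layer, x, training = TRUE)
    dy <- array(rnorm(length(y)), dim = dim(y))
    zero_grads(layer)
    dx <- lv_backward(layer, dy)
    h <- 1e-6
    i <- 23
    xp <- x
    xp[i] <- xp[i] + h
    yp <- lv_forward(layer, xp, training = TRUE)
    lv_backward(layer, dy)                 # clear caches
    fd <- sum((yp - y) * dy) / h
    expect_lt(abs(fd - dx[i]) / max(1e-6, abs(fd)), 1e-3,
              label = layer$type)
  }
})

test_that("strip-convolution pair equals a dense 2D kernel", {
  # a separable 1xk then kx1 depthwise pair with kernels u, v equals one
  # dense kxk convolution with the outer-product kernel (plus bias routing)
  set.seed(13)
  k <- 7
  d <- c(12, 12, 1, 2)
  x <- array(rnorm(prod(d)), dim = d)
  a <- layer_dwconv2d(1, 1, k)             # 1 x k
  b <- layer_dwconv2d(1, k, 1)             # k x 1
  a$b[] <- 0
  b$b[] <- 0
  y <- lv_forward(b, lv_forward(a, x))
  dense <- array(0, dim = c(k, k, 1))
  dense[, , 1] <- outer(as.vector(b$w), as.vector(a$w))
  dn <- layer_dwconv2d(1, k, k)
  dn$w <- dense
  dn$b[] <- 0
  yd <- lv_forward(dn, x)
  interior <- y[4:9, 4:9, , , drop = FALSE] - yd[4:9, 4:9, , , drop = FALSE]
  expect_lt(max(abs(interior)), 1e-5)
})

test_that("trilinear resize is the exact adjoint of its backward", {
  set.seed(14)
  x <- array(rnorm(6 * 5 * 4 * 2), dim = c(6, 5, 4, 2))
  y <- .cpp_trilinear_resize(x, c(12L, 10L, 8L, 2L))
  g <- array(rnorm(length(y)), dim = dim(y))
  gt <- .cpp_trilinear_resize_bwd(g, c(6L, 5L, 4L, 2L))
  expect_lt(abs(sum(y * g) - sum(x * gt)), 1e-9)
})

test_that("slice folding round-trips bit-for-bit", {
  set.seed(15)
  x <- array(rnorm(8 * 7 * 4 * 3), dim = c(8, 7, 4, 3))
  expect_identical(slices_to_volume(volume_to_slices(x)), x)
  x1 <- array(rnorm(8 * 7 * 1 * 3), dim = c(8, 7, 1, 3))
  expect_identical(slices_to_volume(volume_to_slices(x1)), x1)
})
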