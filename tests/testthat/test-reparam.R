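# Structural re-parameterization: normalization folding, branch merging and
# whole-network deployment equivalence.

test_that("identity statistics leave the kernel unchanged", {
  set.seed(20)
  k <- array(rnorm(27 * 2 * 2), dim = c(3, 3, 3, 2, 2))
  br <- branch_weights(k, c(0.3, -0.1),
                       norm_stats = list(mean = c(0, 0), var = c(1, 1),
                                         scale = c(1, 1), shift = c(0, 0),
                                         eps = 0))
  f <- fuse_norm(br)
  expect_equal(f$kernel, k)
  expect_equal(f$bias, c(0.3, -0.1))
})

test_that("folding zero-mean statistics maps bias to bias*scale + shift", {
  set.seed(21)
  k <- array(rnorm(2 * 3), dim = c(1, 1, 1, 2, 3))
  bias <- c(0.5, -0.2, 1.1)
  sc <- c(2, 0.5, 1.5)
  sh <- c(0.1, 0.2, 0.3)
  f <- fuse_norm(branch_weights(k, bias,
                                norm_stats = list(mean = rep(0, 3),
                                                  var = rep(1, 3),
                                                  scale = sc, shift = sh,
                                                  eps = 0)))
  expect_equal(f$bias, bias * sc + sh)
})

test_that("folded branch output equals conv followed by normalization", {
  set.seed(22)
  for (rep in 1:20) {
    cin <- 2
    cout <- 3
    k <- array(rnorm(27 * cin * cout), dim = c(3, 3, 3, cin, cout))
    bias <- rnorm(cout)
    ns <- list(mean = rnorm(cout), var = runif(cout, 0.2, 2),
               scale = rnorm(cout), shift = rnorm(cout), eps = 1e-5)
    x <- array(rnorm(6 * 5 * 4 * cin), dim = c(6, 5, 4, cin))
    raw <- .cpp_conv3d_fwd(x, k, 1L)
    raw <- raw + rep(bias, each = prod(dim(raw)[1:3]))
    normed <- raw
    for (c in seq_len(cout))
      normed[, , , c] <- (raw[, , , c] - ns$mean[c]) /
        sqrt(ns$var[c] + ns$eps) * ns$scale[c] + ns$shift[c]
    f <- fuse_norm(branch_weights(k, bias, ns))
    fused <- .cpp_conv3d_fwd(x, f$kernel, 1L)
    fused <- fused + rep(f$bias, each = prod(dim(fused)[1:3]))
    expect_lt(max(abs(fused - normed)), 1e-5)
  }
})

test_that("merging sums kernels at the center tap and handles identity", {
  w1 <- array(2, dim = c(1, 1, 1, 1, 1))
  w2 <- array(3, dim = c(1, 1, 1, 1, 1))
  m <- merge_branches(list(branch_weights(w1), branch_weights(w2)), 1L)
  expect_equal(as.vector(m$kernel), 5)

  set.seed(23)
  k3 <- array(rnorm(27 * 4), dim = c(3, 3, 3, 2, 2))
  m2 <- merge_branches(list(branch_weights(k3), identity_branch(2)), 3L)
  x <- array(rnorm(5 * 5 * 4 * 2), dim = c(5, 5, 4, 2))
  merged_out <- .cpp_conv3d_fwd(x, m2$kernel, 1L)
  sum_out <- .cpp_conv3d_fwd(x, k3, 1L) + x
  expect_lt(max(abs(merged_out - sum_out)), 1e-5)

  single <- merge_branches(list(branch_weights(k3)), 3L)
  expect_equal(single$kernel, k3)
})

test_that("merge rejects incompatible inputs", {
  k <- array(0, dim = c(3, 3, 3, 2, 2))
  expect_error(merge_branches(list(branch_weights(k)), 4L), "odd")
  k2 <- array(0, dim = c(3, 3, 3, 3, 2))
  expect_error(merge_branches(list(branch_weights(k), branch_weights(k2))),
               "incompatible")
  expect_error(branch_weights(array(0, dim = c(2, 2, 2, 1, 1))), "odd")
})

test_that("deployed network reproduces eval outputs and shrinks", {
  net <- tiny_net("elanres-unet", seed = 30)
  set.seed(31)
  # populate normalization running statistics with a few training passes
  for (i in 1:3)
    invisible(network_forward(net, array(rnorm(16 * 16 * 8),
                                         dim = c(16, 16, 8, 1)),
                              training = TRUE))
  x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8, 1))
  before <- network_forward(net, x, training = FALSE)
  n_before <- count_parameters(net)
  net <- convert_to_deploy(net)
  after <- network_forward(net, x, training = FALSE)
  expect_lt(max(abs(before - after)), 1e-4)
  expect_lt(count_parameters(net), n_before)
  expect_true(is_deployed(net))
  expect_warning(convert_to_deploy(net), "already deployed")
})

test_that("zero unit kernels leave only the bias path after deployment", {
  net <- tiny_net("elanres-unet", seed = 32)
  for (unit in liverseg:::rep_units_of(net)) {
    for (cv in unit$children$b3) cv$w[] <- 0
    unit$children$b1$w[] <- 0
  }
  set.seed(33)
  for (i in 1:2)
    invisible(network_forward(net, array(rnorm(16 * 16 * 8),
                                         dim = c(16, 16, 8, 1)),
                              training = TRUE))
  x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8, 1))
  before <- network_forward(net, x, training = FALSE)
  after <- network_forward(convert_to_deploy(net), x, training = FALSE)
  expect_lt(max(abs(before - after)), 1e-5)
})
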