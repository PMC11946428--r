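# Cascade mechanics: component selection against a flood-fill oracle, ROI
# boxes, sliding-window invariances and containment clamping.

test_that("largest component matches the flood-fill oracle", {
  set.seed(60)
  for (i in 1:20) {
    m <- random_mask(c(12, 12, 12), 0.2)
    if (!any(m)) next
    lab <- label_bruteforce(m)
    sizes <- tabulate(lab[lab > 0])
    kept <- largest_component(m)
    expect_equal(sum(kept), max(sizes))
    # the kept region is one of the oracle's components
    ids <- unique(lab[kept])
    expect_length(ids, 1)
    expect_equal(sum(lab == ids), sum(kept))
  }
})

test_that("largest component edge cases", {
  m <- array(FALSE, dim = c(10, 5, 5))
  m[1:2, 1, 1] <- TRUE                       # size 2
  m[5:9, 3, 3] <- TRUE                       # size 5
  expect_equal(sum(largest_component(m) & m[5:9, 3, 3]), 5)
  expect_equal(sum(largest_component(m)), 5)
  single <- array(FALSE, dim = c(4, 4, 4))
  single[2, 2, 2] <- TRUE
  expect_identical(largest_component(single), single)
  empty <- array(FALSE, dim = c(4, 4, 4))
  expect_identical(largest_component(empty), empty)
})

test_that("liver ROI boxes expand and clip correctly", {
  m <- array(FALSE, dim = c(20, 20, 20))
  m[5:12, 5:12, 5:12] <- TRUE                # 0-based [4, 12)
  r0 <- liver_roi(m, 0)
  expect_identical(r0$lo, c(4L, 4L, 4L))
  expect_identical(r0$hi, c(12L, 12L, 12L))
  r10 <- liver_roi(m, 10)
  expect_identical(r10$lo, c(0L, 0L, 0L))
  expect_identical(r10$hi, c(20L, 20L, 20L))
  r_all <- liver_roi(m, 20)
  expect_identical(r_all$hi - r_all$lo, dim(m))
  expect_error(liver_roi(array(FALSE, dim = c(4, 4, 4))), "empty")
})

test_that("sliding window averages to a constant for a constant model", {
  net <- tiny_net("unet", widths = c(4, 4, 4, 4), seed = 61)
  # zero every weight; the final head bias fixes a constant logit
  for (l in collect_layers(net)) for (p in l$params) l[[p]][] <- 0
  net$children$head3$children$conv$b[] <- 1.2
  vol <- array(runif(24 * 24 * 16), dim = c(24, 24, 16))
  p0 <- sliding_window_predict(net, vol, c(16, 16, 8), overlap = 0)
  p5 <- sliding_window_predict(net, vol, c(16, 16, 8), overlap = 0.5)
  expect_identical(dim(p0), dim(vol))
  expect_lt(max(abs(p0 - 1 / (1 + exp(-1.2)))), 1e-12)
  expect_lt(max(abs(p0 - p5)), 1e-12)
  # volume smaller than the patch: pad-and-crop keeps the input shape
  small <- array(runif(10 * 10 * 6), dim = c(10, 10, 6))
  ps <- sliding_window_predict(net, small, c(16, 16, 8))
  expect_identical(dim(ps), dim(small))
  expect_error(sliding_window_predict(net, vol, c(15, 16, 8)), "divisible")
})

test_that("sliding window is deterministic for fixed weights", {
  net <- tiny_net("unet", widths = c(4, 6, 8, 10), seed = 62)
  vol <- array(runif(24 * 24 * 16), dim = c(24, 24, 16))
  expect_identical(sliding_window_predict(net, vol, c(16, 16, 8)),
                   sliding_window_predict(net, vol, c(16, 16, 8)))
})

test_that("a saturated tumor model is clamped to the liver mask", {
  set.seed(63)
  netL <- tiny_net("unet", widths = c(4, 6, 8, 10), seed = 63)
  netT <- tiny_net("unet", widths = c(4, 4, 4, 4), seed = 64)
  for (l in collect_layers(netT)) for (p in l$params) l[[p]][] <- 0
  netT$children$head3$children$conv$b[] <- 50    # predicts tumor everywhere
  ph <- generate_phantom(phantom_spec(seed = 65))
  res <- two_stage_predict(netL, netT, ph$volume,
                           patch_size = c(64, 64, 32))
  expect_true(all(res$tumor$voxels <= res$liver$voxels))
  expect_identical(dim(res$label_map), dim(ph$volume$voxels))
  if (any(res$liver$voxels))
    expect_identical(res$tumor$voxels, res$liver$voxels & res$tumor$voxels)
  expect_true(all(res$label_map[res$tumor$voxels] == 2L))
  expect_true(all(res$label_map[res$liver$voxels & !res$tumor$voxels] == 1L))
})
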