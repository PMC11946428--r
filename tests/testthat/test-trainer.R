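# Optimization schedule closed forms, deterministic splits and sampling,
# and a desk-scale overfitting sanity run.

test_that("step-decayed learning rate follows its closed form", {
  expect_equal(lr_at_epoch(0), 1e-4)
  expect_equal(lr_at_epoch(30), 8e-5)
  expect_equal(lr_at_epoch(60), 6.4e-5)
  expect_equal(lr_at_epoch(29), 1e-4)
  eps <- 0:120
  lr <- lr_at_epoch(eps)
  expect_true(all(diff(lr) <= 0))
  expect_equal(length(unique(lr)), 5)     # piecewise constant, 30-epoch steps
})

test_that("3:1 splits are sized, disjoint, exhaustive and deterministic", {
  s <- make_splits(1:111, 0.75, seed = 2)
  expect_length(s$train, 83)
  expect_length(s$val, 28)
  expect_length(intersect(s$train, s$val), 0)
  expect_setequal(c(s$train, s$val), 1:111)
  s8 <- make_splits(1:8, 0.75, seed = 2)
  expect_length(s8$train, 6)
  expect_length(s8$val, 2)
  expect_identical(make_splits(1:20, seed = 7), make_splits(1:20, seed = 7))
  expect_error(make_splits(1:3), "at least 4")
})

test_that("patch sampling honors the oversampling contract", {
  set.seed(70)
  vol <- array(rnorm(24 * 24 * 16), dim = c(24, 24, 16))
  lab <- array(0L, dim = dim(vol))
  lab[10:14, 10:14, 6:10] <- 1L
  for (i in 1:10) {
    pa <- liverseg:::sample_patch(vol, lab, c(8, 8, 8),
                                  oversample_fraction = 1)
    expect_gt(sum(pa$target), 0)
  }
  set.seed(71)
  a <- liverseg:::sample_patch(vol, lab, c(8, 8, 8), 0.5)
  set.seed(71)
  b <- liverseg:::sample_patch(vol, lab, c(8, 8, 8), 0.5)
  expect_identical(a$origin, b$origin)
  empty <- array(0L, dim = dim(vol))
  expect_warning(liverseg:::sample_patch(vol, empty, c(8, 8, 8), 1),
                 "no foreground")
})

test_that("a tiny model overfits a phantom and training is deterministic", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 16),
                                      spacing = c(2, 2, 4),
                                      body_semiaxes = c(44, 40, 60),
                                      liver_semiaxes = c(22, 18, 18),
                                      liver_center = c(-6, -4, 0),
                                      n_tumors = 1L,
                                      tumor_radius_range = c(5, 7),
                                      seed = 72))
  x <- window_normalize(ph$volume)$voxels
  cases <- list(list(volume = x, label = ph$label))
  cfg <- train_config(epochs = 5L, steps_per_epoch = 15L,
                      patch_size = c(24, 24, 8), lr0 = 3e-3, seed = 73)
  set.seed(73)
  net <- build_network(network_preset("unet", stage_channels = c(4, 8, 12, 16)))
  res <- train_stage(net, cases, cfg, stage = "liver")
  first <- mean(head(res$history$total_loss, 5))
  last <- mean(tail(res$history$total_loss, 5))
  expect_lt(last, first * 0.5)            # loss halves while overfitting
  expect_true(all(is.finite(res$history$total_loss)))

  set.seed(73)
  net2 <- build_network(network_preset("unet", stage_channels = c(4, 8, 12, 16)))
  res2 <- train_stage(net2, cases, cfg, stage = "liver")
  expect_identical(res$history$total_loss, res2$history$total_loss)
})

test_that("stage-2 cases are cropped to the liver ROI", {
  lab <- array(0L, dim = c(30, 30, 10))
  lab[10:20, 12:22, 3:7] <- 1L
  lab[14:16, 15:17, 4:6] <- 2L
  vol <- array(rnorm(length(lab)), dim = dim(lab))
  cr <- liverseg:::crop_case_to_roi(vol, lab, margin = 2L)
  expect_identical(dim(cr$label), c(15L, 15L, 9L))
  expect_true(all(cr$label[cr$label == 2L] == 2L))
  expect_equal(sum(cr$label == 2L), sum(lab == 2L))
})
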