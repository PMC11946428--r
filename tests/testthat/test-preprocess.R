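# Preprocessing geometry: body extraction, crop arithmetic, windowing and
# exact restoration.

test_that("HU windowing maps endpoints, midpoint and clips", {
  v <- ct_volume(array(c(-200, 200, 0, 500, -1000, 37),
                       dim = c(6, 1, 1)), c(1, 1, 1), "HU")
  n <- window_normalize(v)
  expect_equal(n$voxels[1:5], c(0, 1, 0.5, 1, 0))
  expect_equal(n$intensity_kind, "normalized")
  expect_true(all(n$voxels >= 0 & n$voxels <= 1))
  # already-normalized input passes through unchanged
  expect_identical(window_normalize(n), n)
  # monotone in HU
  hu <- sort(runif(50, -400, 400))
  nv <- window_normalize(ct_volume(array(hu, dim = c(50, 1, 1))))$voxels
  expect_true(all(diff(as.vector(nv)) >= 0))
  # signed alternative maps to [-1, 1]
  s <- window_normalize(v, mode = "signed")
  expect_equal(s$voxels[1:2], c(-1, 1))
})

test_that("crop box arithmetic: tight box, margins, clipping", {
  vox <- array(0, dim = c(30, 30, 30))
  body <- array(FALSE, dim = c(30, 30, 30))
  body[11:20, 11:20, 11:20] <- TRUE           # 0-based [10, 20)
  vol <- ct_volume(vox, c(1, 1, 1), "HU")
  bm <- ct_mask(body, c(1, 1, 1))

  cr0 <- crop_to_body(vol, bm, margin_vox = 0)
  expect_identical(dim(cr0$volume$voxels), c(10L, 10L, 10L))
  expect_identical(cr0$record$crop_lo, c(10L, 10L, 10L))
  expect_identical(cr0$record$crop_hi, c(20L, 20L, 20L))

  cr2 <- crop_to_body(vol, bm, margin_vox = 2)
  expect_identical(cr2$record$crop_lo, c(8L, 8L, 8L))
  expect_identical(cr2$record$crop_hi, c(22L, 22L, 22L))

  edge <- array(FALSE, dim = c(30, 30, 30))
  edge[1:4, 1:4, 1:4] <- TRUE
  cre <- crop_to_body(vol, ct_mask(edge, c(1, 1, 1)), margin_vox = 5)
  expect_identical(cre$record$crop_lo, c(0L, 0L, 0L))
  expect_identical(cre$record$crop_hi, c(9L, 9L, 9L))

  expect_error(crop_to_body(vol, ct_mask(body & FALSE, c(1, 1, 1))),
               "empty")
})

test_that("body mask recovers the phantom body within a voxel boundary", {
  ph <- generate_phantom(phantom_spec(seed = 7))
  bm <- compute_body_mask(ph$volume)
  truth <- ph$truth$body_mask
  # agreement away from the boundary: every disagreeing voxel must touch
  # the analytic boundary (one-voxel tolerance)
  disagree <- xor(bm$voxels, truth)
  interior <- truth & !extract_surface(truth)$voxels
  grown <- .cpp_binary_morph(truth, 1L, TRUE)
  expect_equal(sum(disagree & interior), 0)
  expect_equal(sum(bm$voxels & !grown), 0)
  expect_gt(dice_score(bm$voxels, truth), 0.98)
  # single connected component by construction
  lab <- .cpp_label_components(bm$voxels, 26L)
  expect_equal(max(lab), 1)
})

test_that("body mask threshold contracts hold", {
  flat_air <- ct_volume(array(-1000, dim = c(8, 8, 8)), c(1, 1, 1), "HU")
  expect_error(compute_body_mask(flat_air), "empty body")
  flat0 <- ct_volume(array(0, dim = c(8, 8, 8)), c(1, 1, 1), "HU")
  expect_true(all(compute_body_mask(flat0)$voxels))
})

test_that("in-plane resampling halves x/y, keeps z and physical extent", {
  v <- ct_volume(array(rnorm(64 * 64 * 10), dim = c(64, 64, 10)),
                 c(0.7, 0.7, 2.5), "HU")
  r <- resample_inplane(v, 0.5)
  expect_identical(dim(r$voxels), c(32L, 32L, 10L))
  expect_equal(r$spacing, c(1.4, 1.4, 2.5))
  expect_equal(dim(r$voxels)[1] * r$spacing[1],
               dim(v$voxels)[1] * v$spacing[1])
  expect_identical(resample_inplane(v, 1), v)
  const <- ct_volume(array(3.5, dim = c(16, 16, 4)), c(1, 1, 1), "HU")
  expect_true(all(resample_inplane(const, 0.5)$voxels == 3.5))
  expect_error(resample_inplane(v, 0), "factor")
})

test_that("restoration inverts the crop/resample geometry", {
  ph <- generate_phantom(phantom_spec(seed = 8))
  liver <- ct_mask(ph$label >= 1L, ph$volume$spacing)
  body <- compute_body_mask(ph$volume)
  cr <- crop_to_body(ph$volume, body, margin_vox = 5)
  rec <- cr$record
  lo <- rec$crop_lo
  hi <- rec$crop_hi
  cropped <- liver$voxels[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                          (lo[3] + 1):hi[3], drop = FALSE]
  small <- resample_inplane(ct_mask(cropped, ph$volume$spacing), 0.5)
  back <- restore_to_original(small, rec)
  expect_identical(dim(back$voxels), dim(liver$voxels))
  expect_gt(dice_score(back, liver), 0.95)

  # factor 1 with a full-grid crop is the identity
  d <- dim(liver$voxels)
  rec1 <- preprocess_record(d, ph$volume$spacing, c(0, 0, 0), d,
                            inplane_scale = 1)
  expect_identical(restore_to_original(liver, rec1)$voxels, liver$voxels)

  # empty stays empty at original shape
  empty <- ct_mask(array(FALSE, dim = liverseg:::processed_shape(rec)),
                   c(1, 1, 1))
  expect_identical(sum(restore_to_original(empty, rec)$voxels), 0L)

  wrong <- ct_mask(array(FALSE, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_error(restore_to_original(wrong, rec), "does not match")
})
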