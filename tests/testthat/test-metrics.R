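# Metric suite: counting identities, surface extraction, exact surface
# distances against the all-pairs oracle, lesion sizing and stratification.

test_that("Dice score matches direct counting and empty conventions", {
  m <- random_mask(c(6, 6, 6), 0.4)
  expect_equal(dice_score(m, m), 1)
  a <- array(FALSE, dim = c(4, 4, 4))
  b <- a
  a[1:2, 1, 1] <- TRUE
  b[3:4, 4, 4] <- TRUE
  expect_equal(dice_score(a, b), 0)
  expect_equal(dice_score(a & FALSE, b & FALSE), 1)   # both empty
  a2 <- array(FALSE, dim = c(4, 4, 4))
  b2 <- array(FALSE, dim = c(4, 4, 4))
  a2[1:8] <- TRUE
  b2[5:12] <- TRUE
  expect_equal(dice_score(a2, b2), 0.5)               # |A|=|B|=8, overlap 4
  expect_error(dice_score(a, array(FALSE, dim = c(5, 4, 4))), "shapes")
})

test_that("Dice equals 2TP/(2TP+FP+FN) on random masks", {
  set.seed(50)
  for (i in 1:20) {
    A <- random_mask(c(8, 8, 8), 0.35)
    B <- random_mask(c(8, 8, 8), 0.35)
    tp <- sum(A & B)
    fp <- sum(A & !B)
    fn <- sum(!A & B)
    if (tp + fp + fn == 0) next
    expect_equal(dice_score(A, B), 2 * tp / (2 * tp + fp + fn),
                 tolerance = 1e-12)
  }
})

test_that("surface extraction follows the 6-neighbor convention", {
  single <- array(FALSE, dim = c(3, 3, 3))
  single[2, 2, 2] <- TRUE
  expect_equal(sum(extract_surface(single)$voxels), 1)

  cube <- array(FALSE, dim = c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- TRUE
  expect_equal(sum(extract_surface(cube)$voxels), 26)  # all but the center

  slab <- array(TRUE, dim = c(4, 4, 1))               # grid border outside
  expect_equal(sum(extract_surface(slab)$voxels), 16)
  expect_error(extract_surface(array(FALSE, dim = c(2, 2, 2))), "empty")
})

test_that("ASD matches hand cases and scales with spacing", {
  a <- array(FALSE, dim = c(8, 4, 4))
  b <- a
  a[2, 2, 2] <- TRUE
  b[5, 2, 2] <- TRUE
  expect_equal(asd(a, b, c(1, 1, 1)), 3)
  expect_equal(asd(a, b, c(0.5, 1, 1)), 1.5)
  expect_equal(asd(a, a, c(1, 1, 1)), 0)
  expect_error(asd(a, b & FALSE), "empty")
})

test_that("distance-transform ASD equals the all-pairs oracle exactly", {
  set.seed(51)
  for (i in 1:10) {
    A <- random_mask(c(16, 16, 16), 0.3)
    B <- random_mask(c(16, 16, 16), 0.3)
    sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2), runif(1, 0.5, 3))
    expect_equal(asd(A, B, sp), asd_bruteforce(A, B, sp), tolerance = 1e-9)
  }
})

test_that("metrics are symmetric / dual as expected", {
  set.seed(52)
  A <- random_mask(c(10, 10, 10), 0.3)
  B <- random_mask(c(10, 10, 10), 0.3)
  expect_equal(dice_score(A, B), dice_score(B, A))
  expect_equal(asd(A, B), asd(B, A))
  expect_equal(rvd(A, A), 0)
  expect_equal(precision_recall(A, B)[["precision"]],
               precision_recall(B, A)[["recall"]])
})

test_that("metrics are invariant under simultaneous axis permutation", {
  set.seed(53)
  A <- random_mask(c(9, 7, 5), 0.3)
  B <- random_mask(c(9, 7, 5), 0.3)
  sp <- c(1.1, 0.7, 2.3)
  perm <- c(3, 1, 2)
  Ap <- aperm(A, perm)
  Bp <- aperm(B, perm)
  expect_equal(dice_score(A, B), dice_score(Ap, Bp))
  expect_equal(asd(A, B, sp), asd(Ap, Bp, sp[perm]), tolerance = 1e-12)
  expect_equal(sort(major_axis_length(A, sp)),
               sort(major_axis_length(Ap, sp[perm])), tolerance = 1e-12)
})

test_that("RVD and precision/recall match direct arithmetic", {
  A <- array(FALSE, dim = c(10, 10, 2))
  A[1:100] <- TRUE
  B <- array(FALSE, dim = c(10, 10, 2))
  B[1:102] <- TRUE
  expect_equal(rvd(A, B), 0.02)
  expect_equal(rvd(A, B & FALSE), -1)
  expect_error(rvd(A & FALSE, B), "empty")

  # TP = 4, FP = 4, FN = 12
  P <- array(FALSE, dim = c(5, 5, 1))
  G <- array(FALSE, dim = c(5, 5, 1))
  P[1:8] <- TRUE
  G[5:20] <- TRUE
  pr <- precision_recall(P, G)
  expect_equal(pr[["precision"]], 0.5)
  expect_equal(pr[["recall"]], 0.25)
  # strict subset: precision 1, recall |A|/|B|
  S <- G
  S[] <- FALSE
  S[5:10] <- TRUE
  pr2 <- precision_recall(S, G)
  expect_equal(pr2[["precision"]], 1)
  expect_equal(pr2[["recall"]], 6 / 16)
})

test_that("major-axis lengths are Feret diameters per 26-component", {
  single <- array(FALSE, dim = c(5, 5, 5))
  single[3, 3, 3] <- TRUE
  expect_equal(major_axis_length(single), 0)

  rod <- array(FALSE, dim = c(3, 3, 13))
  rod[2, 2, 2:12] <- TRUE
  expect_equal(major_axis_length(rod), 10)

  expect_length(major_axis_length(array(FALSE, dim = c(4, 4, 4))), 0)

  two <- array(FALSE, dim = c(12, 6, 6))
  two[1:3, 1, 1] <- TRUE                   # length 2
  two[8:12, 3, 3] <- TRUE                  # length 4
  expect_equal(sort(major_axis_length(two)), c(2, 4))
})

test_that("Dice stratification splits at the boundary and averages sizes", {
  cases <- data.frame(dice = c(1, 1), lengths_mm = c("10", "12"))
  s <- stratify_cases(cases)
  expect_equal(s$n_cases[s$group == "low"], 0)

  cases2 <- data.frame(dice = c(0.59, 0.60), lengths_mm = c("5", "7"))
  s2 <- stratify_cases(cases2)
  expect_equal(s2$n_cases, c(1, 1))
  expect_equal(s2$mean_major_axis_mm[s2$group == "high"], 7)

  cases3 <- data.frame(dice = c(0.9, 0.2))
  cases3$lengths_mm <- I(list(c(10, 20), c(40)))
  s3 <- stratify_cases(cases3)
  expect_equal(s3$mean_major_axis_mm, c(15, 40))

  expect_equal(nrow(stratify_cases(data.frame())), 0)
})
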