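# Loss arithmetic against hand-derived values, endpoint identities and the
# deep-supervision schedule.

test_that("soft Dice loss matches hand-derived cases", {
  ones <- rep(1, 8)
  expect_lt(dice_loss(ones, ones), 1e-5)
  expect_gt(dice_loss(rep(0, 8), c(1, rep(0, 7))), 1 - 1e-4)
  expect_equal(dice_loss(c(0.5, 0.5), c(1, 0)), 0.5, tolerance = 1e-5)
})

test_that("Tversky loss matches hand-derived cases and the Dice identity", {
  expect_lt(tversky_loss(rep(1, 4), rep(1, 4)), 1e-5)
  expect_equal(tversky_loss(c(1, 0), c(0, 1)), 1, tolerance = 1e-5)
  set.seed(40)
  for (i in 1:10) {
    p <- runif(20)
    y <- rbinom(20, 1, 0.4)
    # alpha = beta = 1/2 turns the Tversky index into the Dice index
    tv <- tversky_loss(p, y, alpha = 0.5, beta = 0.5, epsilon = 0)
    di <- 1 - 2 * sum(p * y) / (sum(p) + sum(y))
    expect_equal(tv, di, tolerance = 1e-6)
  }
})

test_that("cross-entropy matches closed forms", {
  y <- rbinom(16, 1, 0.5)
  expect_equal(bce_loss(rep(0.5, 16), y), log(2), tolerance = 1e-6)
  expect_lt(bce_loss(y, y), 1e-6)
  expect_equal(bce_loss(exp(-1), 1), 1, tolerance = 1e-6)
})

test_that("hybrid losses interpolate their components", {
  set.seed(41)
  p <- runif(30)
  y <- rbinom(30, 1, 0.3)
  expect_equal(hybrid1_loss(p, y, lambda = 0), dice_loss(p, y))
  expect_equal(hybrid1_loss(p, y, lambda = 1), bce_loss(p, y))
  expect_equal(hybrid2_loss(p, y, lambda = 0), tversky_loss(p, y))
  expect_equal(hybrid2_loss(p, y, lambda = 1), bce_loss(p, y))
  expect_equal(hybrid1_loss(p, y, lambda = 0.5),
               (dice_loss(p, y) + bce_loss(p, y)) / 2, tolerance = 1e-9)
  expect_error(hybrid1_loss(p, y, lambda = 1.5), "lambda")
})

test_that("deep-supervision total and weight decay follow the schedule", {
  expect_equal(deep_supervision_total(c(1, 1, 1, 1), 0.4), 2.2)
  expect_equal(deep_supervision_total(c(0.1, 0.2, 0.3, 0.4), 0.4), 0.64)
  expect_equal(deep_supervision_total(c(0.5, 0.5, 0.5, 0.7), 0), 0.7)
  expect_error(deep_supervision_total(c(1, 1, 1), 0.4), "exactly 4")
  a <- 0.4
  iterates <- a
  for (i in 1:3) {
    a <- decay_ds_alpha(a)
    iterates <- c(iterates, a)
  }
  expect_equal(iterates, c(0.4, 0.32, 0.256, 0.2048))
  expect_equal(decay_ds_alpha(0), 0)
})

test_that("losses are permutation invariant over voxels", {
  set.seed(42)
  p <- runif(40)
  y <- rbinom(40, 1, 0.4)
  perm <- sample(40)
  for (nm in c("dice", "tversky", "bce", "hybrid1", "hybrid2")) {
    f <- get_loss(nm)
    expect_equal(f(p, y), f(p[perm], y[perm]), tolerance = 1e-12,
                 label = nm)
  }
})

test_that("logit-space gradients match finite differences for every loss", {
  set.seed(43)
  z <- rnorm(25)
  y <- rbinom(25, 1, 0.4)
  h <- 1e-6
  for (nm in c("dice", "tversky", "bce", "hybrid1", "hybrid2")) {
    g <- loss_grad_logits(nm, z, y)
    for (i in c(3, 11)) {
      zp <- z
      zp[i] <- zp[i] + h
      fd <- (loss_grad_logits(nm, zp, y)$loss - g$loss) / h
      expect_lt(abs(fd - g$dz[i]) / max(1e-6, abs(fd)), 1e-3,
                label = paste(nm, i))
    }
  }
})
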