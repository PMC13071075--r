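# Compound objective: closed forms, additivity, oracle agreement, gradients.

test_that("segmentation cross-entropy matches closed forms", {
  # single voxel, uniform prediction -> ln 2
  p <- array(c(0.5, 0.5), c(1, 1, 1, 2))
  expect_equal(ce_seg_loss(p, array(1, c(1, 1, 1))), log(2), tolerance = 1e-12)
  # perfect one-hot predictions -> 0
  y <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
  ph <- array(0, c(3, 3, 3, 2))
  ph[, , , 2] <- y; ph[, , , 1] <- 1 - y
  expect_lt(ce_seg_loss(ph, y), 1e-10)
  # uniform predictions give exactly ln 2 regardless of the mask
  pu <- array(0.5, c(3, 3, 3, 2))
  expect_equal(ce_seg_loss(pu, y), log(2), tolerance = 1e-12)
  expect_equal(ce_seg_loss(pu, 1 - y), log(2), tolerance = 1e-12)
})

test_that("dice loss matches its defining ratio", {
  y <- array(0, c(2, 2, 2)); y[1:4] <- 1          # m = 4 foreground voxels
  ph <- array(0, c(2, 2, 2, 2))
  ph[, , , 2] <- y; ph[, , , 1] <- 1 - y
  expect_equal(dice_loss(ph, y), 0, tolerance = 1e-9)      # perfect overlap
  p0 <- array(0, c(2, 2, 2, 2)); p0[, , , 1] <- 1          # empty prediction
  expect_equal(dice_loss(p0, y), 1 - 1e-5 / (4 + 1e-5), tolerance = 1e-12)
  # p = 0.5 on 2m voxels, y has m foreground
  ph5 <- array(0.5, c(2, 2, 2, 2))
  expect_equal(dice_loss(ph5, y), 1 - (4 + 1e-5) / (8 + 1e-5),
               tolerance = 1e-12)
  # bounded in [0, 1] for random inputs
  set.seed(5)
  for (i in 1:10) {
    pr <- array(runif(16), c(2, 2, 2, 2))
    yr <- array(rbinom(8, 1, 0.5), c(2, 2, 2))
    expect_gte(dice_loss(pr, yr), 0)
    expect_lte(dice_loss(pr, yr), 1)
  }
})

test_that("classification cross-entropy: closed form and batch mean", {
  expect_equal(cls_loss(c(0.5, 0.5), 0), log(2), tolerance = 1e-12)
  expect_lt(cls_loss(matrix(c(1, 0, 0, 1), 2), c(0, 1)), 1e-10)
  p <- matrix(c(0.8, 0.2, 0.3, 0.7), 2)
  a <- cls_loss(p[, 1, drop = FALSE], 0)
  b <- cls_loss(p[, 2, drop = FALSE], 1)
  expect_equal(cls_loss(p, c(0, 1)), (a + b) / 2, tolerance = 1e-12)
})

test_that("total loss satisfies the additivity identities", {
  bd <- loss_breakdown(0.2, 0.3, 0.1)
  expect_equal(bd$l_seg, 0.5)
  expect_equal(bd$l_total, 0.6)
  set.seed(9)
  pr <- array(runif(16), c(2, 2, 2, 2))
  pr2 <- pr; pr2[, , , 1] <- 1 - pr[, , , 2]    # proper per-voxel softmax
  yr <- array(rbinom(8, 1, 0.5), c(2, 2, 2))
  cp <- matrix(c(0.6, 0.4), 2, 1)
  bd <- total_loss(pr2, yr, cp, 1)
  expect_equal(bd$l_total, bd$l_seg + bd$l_cls, tolerance = 1e-14)
  expect_equal(bd$l_seg, bd$l_ce + bd$l_dice, tolerance = 1e-14)
  expect_equal(bd$l_ce, ce_seg_loss(pr2, yr))
  expect_equal(bd$l_dice, dice_loss(pr2, yr))
})

test_that("losses agree with a scalar-loop oracle on a 2^3 patch", {
  set.seed(13)
  p1 <- array(runif(8), c(2, 2, 2))
  probs <- array(0, c(2, 2, 2, 2))
  probs[, , , 2] <- p1; probs[, , , 1] <- 1 - p1
  y <- array(rbinom(8, 1, 0.5), c(2, 2, 2))
  # brute-force voxel loops
  ce <- 0; sp <- 0; sy <- 0; spy <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    yc <- y[i, j, k]
    ce <- ce - (yc * log(p1[i, j, k]) + (1 - yc) * log(1 - p1[i, j, k]))
    sp <- sp + p1[i, j, k]; sy <- sy + yc; spy <- spy + p1[i, j, k] * yc
  }
  ce <- ce / 8
  dice <- 1 - (2 * spy + 1e-5) / (sp + sy + 1e-5)
  cp <- matrix(c(0.3, 0.7), 2, 1)
  bd <- total_loss(probs, y, cp, 1)
  expect_equal(bd$l_ce, ce, tolerance = 1e-12)
  expect_equal(bd$l_dice, dice, tolerance = 1e-12)
  expect_equal(bd$l_total, ce + dice - log(0.7), tolerance = 1e-12)
})

test_that("training (logit-space) losses match the probability-space reference", {
  set.seed(17)
  logits <- array(rnorm(3^3 * 2 * 2), c(3, 3, 3, 2, 2))
  y <- array(rbinom(3^3 * 2, 1, 0.4), c(3, 3, 3, 2))
  sl <- ns$ag_seg_loss(vt_(logits), y)
  probs <- seg_predictions(logits)$probs
  expect_equal(attr(sl, "l_ce"), ce_seg_loss(probs, y), tolerance = 1e-9)
  expect_equal(attr(sl, "l_dice"), dice_loss(probs, y), tolerance = 1e-9)
  zl <- matrix(rnorm(6), 2, 3)
  ez <- exp(zl); pz <- sweep(ez, 2, colSums(ez), "/")
  cl <- ns$ag_cls_loss(vt_(zl), c(1, 0, 1))
  expect_equal(cl$value, cls_loss(pz, c(1, 0, 1)), tolerance = 1e-12)
})

test_that("dice gradient is finite at the perfect prediction", {
  y <- array(0, c(2, 2, 2, 1)); y[1, 1, 1, 1] <- 1
  # logits giving p1 ~= y nearly exactly
  logits <- array(0, c(2, 2, 2, 2, 1))
  logits[, , , 1, 1] <- 20 * (1 - y[, , , 1])
  logits[, , , 2, 1] <- 20 * y[, , , 1]
  lv <- vt_(logits); lv$requires_grad <- TRUE
  sl <- ns$ag_seg_loss(lv, y)
  ag_backward_(sl)
  expect_true(all(is.finite(lv$grad)))
})
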