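# Architectural primitives: group-number rule, MSConv, GSA, DSA, CA.

test_that("group_number matches exhaustive search and handles edge cases", {
  brute <- function(c_in, c_out) {
    best <- 1L
    for (g in seq_len(c_out))
      if (g <= min(c_in %/% 2, c_out) && c_out %% g == 0) best <- g
    best
  }
  for (c_in in c(1:8, 16, 24, 32, 48, 64))
    for (c_out in c(1:8, 16, 24, 32, 48, 64))
      expect_identical(group_number(c_in, c_out), brute(c_in, c_out),
                       info = paste(c_in, c_out))
  expect_identical(group_number(64, 64), 32L)
  expect_identical(group_number(32, 48), 16L)
  expect_identical(group_number(3, 8), 1L)
  expect_identical(group_number(2, 5), 1L)
})

test_that("msconv output equals the sum of four naive branch oracles", {
  set.seed(101)
  for (trial in 1:5) {
    c_in <- sample(c(2, 4, 6, 8), 1)
    c_out <- sample(c(2, 4, 8), 1)
    d <- sample(4:6, 1)
    blk <- msconv_block(c_in, c_out)
    g <- blk$spec$groups
    x <- array(rnorm(d^3 * c_in), c(d, d, d, c_in))
    got <- block_forward(blk, x)
    expected <- 0
    for (nm in c("k1", "k3", "k5", "res")) {
      w <- blk$params[[paste0(nm, ".w")]]$value
      b <- blk$params[[paste0(nm, ".b")]]$value
      k <- dim(w)[1]
      expected <- expected +
        naive_conv3d(x, w, b, pad = (k - 1) %/% 2, groups = g)
    }
    expect_lt(max_rel_err(array(got, dim(expected)), expected), 1e-5)
  }
})

test_that("msconv is linear in its input when biases are zero", {
  set.seed(7)
  blk <- msconv_block(4, 4)
  for (nm in grep("\\.b$", names(blk$params), value = TRUE))
    blk$params[[nm]]$value <- blk$params[[nm]]$value * 0
  x <- array(rnorm(4^3 * 4), c(4, 4, 4, 4))
  y1 <- block_forward(blk, x)
  y2 <- block_forward(blk, 3.5 * x)
  expect_lt(max_rel_err(3.5 * y1, y2), 1e-10)
  # zero weights and biases give a zero output
  for (nm in names(blk$params)) blk$params[[nm]]$value <-
      blk$params[[nm]]$value * 0
  expect_equal(max(abs(block_forward(blk, x))), 0)
})

test_that("attention blocks preserve shape and keep gates in (0,1)", {
  set.seed(11)
  x <- array(rnorm(5 * 4 * 6 * 8 * 2), c(5, 4, 6, 8, 2))
  for (blk in list(gsa_block(8), dsa_block(8), ca_block(8))) {
    y <- block_forward(blk, x)
    expect_identical(dim(y), dim(x))
  }
  g <- gsa_block(8)
  dsc <- lapply(g$descriptors(vt_(x)), function(t) t$value)
  expect_true(all(dsc$avg > 0 & dsc$avg < 1))
  expect_true(all(dsc$max > 0 & dsc$max < 1))
  d <- dsa_block(8)
  maps <- lapply(d$maps(vt_(x)), function(t) t$value)
  expect_true(all(maps$avg > 0 & maps$avg < 1))
  expect_true(all(maps$max > 0 & maps$max < 1))
  ca <- ca_block(8)
  w <- ca$weights(vt_(x))$value
  expect_true(all(w > 0 & w < 1))
})

test_that("gsa with zero projection weights reweights input by 0.25", {
  set.seed(3)
  blk <- gsa_block(4)
  for (nm in c("proj_avg.conv.w", "proj_avg.conv.b",
               "proj_max.conv.w", "proj_max.conv.b"))
    blk$params[[nm]]$value <- blk$params[[nm]]$value * 0
  x <- array(rnorm(4^3 * 4 * 2), c(4, 4, 4, 4, 2))
  d <- blk$descriptors(vt_(x))
  expect_equal(d$avg$value, matrix(0.5, 4, 2), tolerance = 1e-12)
  expect_equal(d$max$value, matrix(0.5, 4, 2), tolerance = 1e-12)
  ns <- asNamespace("nodulemt")
  pre <- ns$ag_scale_channels(ns$ag_scale_channels(vt_(x), d$avg), d$max)
  expect_equal(pre$value, 0.25 * x, tolerance = 1e-12)
})

test_that("dsa max-branch pre-sigmoid map peaks at the dominant voxel", {
  x <- array(0, c(5, 5, 5, 3, 1))
  x[3, 2, 4, 2, 1] <- 10       # one voxel dominates the channel-max
  ns <- asNamespace("nodulemt")
  cm <- ns$ag_chan_max(vt_(x))$value
  expect_equal(which.max(cm), which(array(seq_len(125), c(5, 5, 5)) ==
                                      ((4 - 1) * 25 + (2 - 1) * 5 + 3)))
  expect_equal(max(cm), 10)
})

test_that("ca gives equal channel weights for channel-constant input with tied bottleneck", {
  blk <- ca_block(6, reduction = 2)
  # tie the bottleneck: identical rows/columns make the path symmetric
  blk$params[["fc1.w"]]$value <- matrix(0.1, 3, 6)
  blk$params[["fc1.b"]]$value <- rep(0.05, 3)
  blk$params[["fc2.w"]]$value <- matrix(0.2, 6, 3)
  blk$params[["fc2.b"]]$value <- rep(-0.1, 6)
  x <- array(rep(rnorm(4^3), 6), c(4, 4, 4, 6, 1))  # constant across channels
  w <- blk$weights(vt_(x))$value
  expect_lt(diff(range(w)), 1e-12)
})

test_that("all blocks pass a finite-difference gradient check", {
  set.seed(23)
  x <- array(rnorm(4^3 * 2), c(4, 4, 4, 2, 1))
  for (maker in list(function() msconv_block(2, 2),
                     function() gsa_block(2),
                     function() dsa_block(2, 3),
                     function() ca_block(2))) {
    blk <- maker()
    wgt <- array(rnorm(length(x)), dim(x))
    xv <- vt_(x); xv$requires_grad <- TRUE
    y <- blk$fwd(xv)
    loss <- ns$ag_node(sum(y$value * wgt), list(y), function(g) list(g * wgt))
    ag_backward_(loss)
    f <- function(xa) {
      y <- blk$fwd(vt_(array(xa, dim(x))))
      sum(y$value * wgt)
    }
    expect_lt(max_rel_err(xv$grad, numeric_grad(f, as.numeric(x))), 1e-3)
  }
})
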