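# Synthetic phantom generator: geometry, rendering, cohort contracts.

test_that("unspiculated mask is the discrete ball with the expected volume", {
  spec <- phantom_spec(nodule_radius_mm = 5, spiculation_amplitude = 0,
                      seed = 3)
  m <- make_nodule_mask(spec)
  v_analytic <- 4 / 3 * pi * 5^3
  expect_lt(abs(sum(m) - v_analytic) / v_analytic, 0.10)
  # equals an independently rasterized exact ball
  expect_identical(m, ball_mask(spec$volume_shape, 5))
})

test_that("mask generation is deterministic and single-component", {
  spec <- phantom_spec(nodule_radius_mm = 8, spiculation_amplitude = 0.35,
                      spike_count = 10, seed = 99)
  m1 <- make_nodule_mask(spec)
  m2 <- make_nodule_mask(spec)
  expect_identical(m1, m2)
  # 6-connected flood fill from the center covers the whole foreground
  d <- dim(m1)
  lab <- array(FALSE, d)
  ctr <- ceiling(d / 2)
  queue <- matrix(ctr, 1)
  lab[ctr[1], ctr[2], ctr[3]] <- TRUE
  while (nrow(queue)) {
    nxt <- NULL
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      q <- sweep(queue, 2, -s)
      ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
      q <- q[ok, , drop = FALSE]
      hit <- m1[q] == 1 & !lab[q]
      lab[q[hit, , drop = FALSE]] <- TRUE
      nxt <- rbind(nxt, q[hit, , drop = FALSE])
    }
    queue <- unique(nxt)
    if (is.null(queue)) queue <- matrix(0, 0, 3)
  }
  expect_equal(sum(lab), sum(m1))
})

test_that("oversized nodules are rejected with a geometry error", {
  spec <- phantom_spec(volume_shape = c(24, 24, 24), nodule_radius_mm = 14)
  expect_error(make_nodule_mask(spec), "boundary")
})

test_that("rendered intensities concentrate at the configured means", {
  spec <- phantom_spec(nodule_radius_mm = 7, spiculation_amplitude = 0.2,
                      spike_count = 8, noise_sigma_hu = 40,
                      vessel_count = 2, nodule_hu = -30, seed = 17)
  m <- make_nodule_mask(spec)
  v <- render_phantom(m, spec)
  n <- sum(m)
  expect_lt(abs(mean(v$data[m == 1]) - spec$nodule_hu), 3 * 40 / sqrt(n))
  # rendering is deterministic given the spec
  v2 <- render_phantom(m, spec)
  expect_identical(v$data, v2$data)
  # values stay within the range preprocessing accepts after clipping
  nv <- clip_normalize_hu(v)
  expect_gte(min(nv$data), 0)
  expect_lte(max(nv$data), 1)
})

test_that("noiseless vessel-free phantom is exactly two-valued", {
  spec <- phantom_spec(noise_sigma_hu = 0, vessel_count = 0, seed = 5)
  v <- render_phantom(make_nodule_mask(spec), spec)
  expect_setequal(unique(as.numeric(v$data)),
                  c(spec$background_hu, spec$nodule_hu))
})

test_that("cohort generation honors counts, round-trips, and is deterministic", {
  d1 <- file.path(tempdir(), "coh_det1")
  d2 <- file.path(tempdir(), "coh_det2")
  m1 <- generate_cohort(10, 0.5, seed = 77, out_dir = d1,
                        volume_shape = c(48, 48, 48))
  m2 <- generate_cohort(10, 0.5, seed = 77, out_dir = d2,
                        volume_shape = c(48, 48, 48))
  expect_equal(sum(m1$label == 1), 5)
  expect_equal(sum(m1$label == 0), 5)
  expect_equal(m1$label, m2$label)
  # bit-identical volumes for the same (n, fraction, seed)
  a <- read_volume(file.path(d1, m1$image_path[1]))
  b <- read_volume(file.path(d2, m2$image_path[1]))
  expect_identical(a$data, b$data)
  # every referenced file loads with the header spacing
  man <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 10)
  for (i in seq_len(nrow(man))) {
    vol <- read_volume(file.path(d1, man$image_path[i]))
    msk <- read_volume(file.path(d1, man$mask_path[i]))
    expect_equal(vol$spacing, c(1, 1, 1))
    expect_identical(dim(vol$data), dim(msk$data))
  }
})

test_that("malignant nodules are larger and a volume threshold separates classes", {
  man <- shared_cohort(n = 100L, seed = 123L)
  base <- attr(man, "dir")
  vols <- vapply(seq_len(nrow(man)), function(i)
    sum(read_volume(file.path(base, man$mask_path[i]))$data), numeric(1))
  expect_gt(mean(vols[man$label == 1]), mean(vols[man$label == 0]))
  # trivial foreground-count classifier: best single threshold > 80% accuracy
  thr <- sort(vols)
  acc <- vapply(thr, function(t) mean((vols > t) == (man$label == 1)),
                numeric(1))
  expect_gt(max(acc), 0.8)
})
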