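# Preprocessing chain: resampling, normalization, patch extraction,
# augmentation.

test_that("resampling shape arithmetic and spacing contract", {
  vol <- ct_volume(array(0, c(100, 128, 128)), spacing = c(2.0, 0.7, 0.7))
  rs <- resample_isotropic(vol, NULL, target_mm = 1)
  expect_identical(dim(rs$vol$data), c(200L, 90L, 90L))  # round(128*0.7)=90
  expect_equal(rs$vol$spacing, c(1, 1, 1))
  # full-size case from the shape rule: round(512*0.7) = 358, round(100*2)=200
  expect_identical(as.integer(round(c(100, 512, 512) * c(2, 0.7, 0.7))),
                   c(200L, 358L, 358L))
  expect_error(resample_isotropic(vol, target_mm = -1), "spacing")
  expect_error(
    resample_isotropic(clip_normalize_hu(vol)), "HU")
})

test_that("already-isotropic input is an interpolation identity", {
  set.seed(2)
  vol <- ct_volume(array(rnorm(20^3, -500, 80), c(20, 20, 20)),
                   spacing = c(1, 1, 1))
  m <- array(as.numeric(rbinom(20^3, 1, 0.2)), c(20, 20, 20))
  rs <- resample_isotropic(vol, m)
  expect_equal(rs$vol$data, vol$data, tolerance = 1e-12)
  expect_identical(rs$mask, m)
})

test_that("mask stays binary and its volume is stable under anisotropic resampling", {
  shape <- c(30, 60, 60)
  sp <- c(2.0, 0.7, 0.7)
  m <- ball_mask(shape, 5, spacing = sp)
  vol <- ct_volume(array(-800, shape) + 600 * m, spacing = sp)
  rs <- resample_isotropic(vol, m)
  expect_true(all(rs$mask %in% c(0, 1)))
  # oracle: rasterize the same 5 mm ball at both spacings
  iso <- ball_mask(dim(rs$mask), 5, spacing = c(1, 1, 1))
  expect_lt(abs(sum(rs$mask) - sum(m) * prod(sp)) / (sum(m) * prod(sp)), 0.2)
  expect_gt(dice_coefficient(rs$mask, iso), 0.85)
})

test_that("HU clipping and normalization map endpoints exactly", {
  v <- ct_volume(array(c(-1000, -300, 400, 2000, -5000, 0), c(1, 2, 3)))
  nv <- clip_normalize_hu(v)
  expect_equal(as.numeric(nv$data), c(0, 0.5, 1, 1, 0, 1000 / 1400),
               tolerance = 1e-12)
  expect_identical(nv$intensity, "normalized")
  expect_error(clip_normalize_hu(nv), "already normalized")
  # idempotence on already-clipped inputs: renormalizing the de-normalized
  # volume reproduces itself
  back <- ct_volume(nv$data * 1400 - 1000, spacing = nv$spacing)
  expect_equal(clip_normalize_hu(back)$data, nv$data, tolerance = 1e-12)
})

test_that("patch extraction centers, crops and pads correctly", {
  set.seed(4)
  arr <- array(runif(40^3), c(40, 40, 40))
  vol <- ct_volume(arr, intensity = "normalized")
  msk <- array(rbinom(40^3, 1, 0.1), c(40, 40, 40))
  p <- extract_patch(vol, msk, center = c(20, 21, 22), size = 16, label = 1)
  expect_identical(dim(p$image), c(16L, 16L, 16L))
  # even-size convention: 0-based index 8 = R index 9 holds the center voxel
  expect_equal(p$image[9, 9, 9], arr[20, 21, 22])
  expect_equal(p$mask[9, 9, 9], msk[20, 21, 22])
  # crop semantics: mask equals the intersection with the window
  expect_equal(p$mask, msk[12:27, 13:28, 14:29])
  # corner center: full size, out-of-volume region padded with zero
  pc <- extract_patch(vol, msk, center = c(1, 1, 1), size = 16)
  expect_identical(dim(pc$image), c(16L, 16L, 16L))
  # half = 8 leading planes on each axis fall outside the volume
  expect_true(all(pc$image[1:8, , ] == 0))
  expect_true(all(pc$image[, 1:8, ] == 0))
  # exact padded voxel count from geometry: 16^3 - 8^3
  expect_equal(sum(pc$image == 0), 16^3 - 8^3)
  expect_error(extract_patch(vol, msk, center = c(0, 5, 5), size = 16),
               "outside")
})

test_that("augmentation: identity at zero probability, flip involution, label fixed", {
  set.seed(6)
  img <- array(runif(16^3), c(16, 16, 16))
  msk <- ball_mask(c(16, 16, 16), 4)
  p <- labeled_patch(img, msk, label = 1)
  id <- augment_patch(p, augment_config(0, 0, 0, 0), seed = 9)
  expect_identical(id$image, img)
  expect_identical(id$mask, msk)
  # same seed applies the same flips; flipping twice restores the original
  flip_cfg <- augment_config(0, 0, 1, 0)
  f1 <- augment_patch(p, flip_cfg, seed = 11)
  f2 <- augment_patch(f1, flip_cfg, seed = 11)
  expect_identical(f2$image, img)
  expect_identical(f2$mask, msk)
  expect_false(identical(f1$image, img))
  expect_equal(f1$label, 1L)
})

test_that("elastic deformation keeps masks binary with bounded volume change", {
  msk <- ball_mask(c(32, 32, 32), 8)
  img <- 0.1 + 0.5 * msk
  p <- labeled_patch(img, msk, label = 0)
  cfg <- augment_config(0, 1, 0, 0)
  for (s in c(21, 22, 23)) {
    a <- augment_patch(p, cfg, seed = s)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_lt(abs(sum(a$mask) - sum(msk)) / sum(msk), 0.15)
  }
})

test_that("geometric transforms move image and mask together", {
  # noiseless two-valued phantom: thresholding the transformed image must
  # reproduce the transformed mask exactly (Dice 1)
  msk <- ball_mask(c(24, 24, 24), 6)
  img <- 0.2 + 0.6 * msk
  p <- labeled_patch(img, msk, label = 0)
  for (cfg in list(augment_config(1, 0, 0, 0), augment_config(0, 0, 1, 0),
                   augment_config(1, 0, 1, 0))) {
    a <- augment_patch(p, cfg, seed = 31)
    expect_equal(dice_coefficient(as.numeric(a$image > 0.5), a$mask), 1)
  }
  # elastic: nearest-neighbour mask vs thresholded trilinear image agree
  # away from the interpolation band
  ae <- augment_patch(p, augment_config(0, 1, 0, 0), seed = 33)
  expect_gt(dice_coefficient(as.numeric(ae$image > 0.5), ae$mask), 0.97)
})

test_that("manifest rows load into valid network-ready patches", {
  man <- shared_cohort(n = 8L)
  p <- load_patch(man, 1, patch_size = 32L)
  expect_s3_class(p, "labeled_patch")
  expect_identical(dim(p$image), c(32L, 32L, 32L))
  expect_true(all(p$image >= 0 & p$image <= 1))
  expect_true(all(p$mask %in% c(0, 1)))
  expect_gt(sum(p$mask), 0)
  expect_equal(p$label, man$label[1])
})
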