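# Evaluation harness: confusion counts, Dice, mIoU, classification metrics,
# aggregation.

test_that("confusion counts match hand enumeration", {
  g <- c(rep(1, 10), rep(0, 10))
  p <- g
  p[c(1, 2)] <- 0          # 2 misses
  p[c(11, 12)] <- 1        # 2 false alarms
  cc <- confusion_counts(p, g)
  expect_equal(unclass(cc), list(tp = 8, fp = 2, fn = 2, tn = 8))
  ident <- confusion_counts(g, g)
  expect_equal(c(ident$tp, ident$fp, ident$fn, ident$tn), c(10, 0, 0, 10))
  comp <- confusion_counts(1 - g, g)
  expect_equal(c(comp$tp, comp$tn), c(0, 0))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "shape")
})

test_that("dice coefficient matches set arithmetic", {
  a <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 1, 1, 1, 0, 0, 0)   # |A|=4, |B|=6, |A∩B|=3
  expect_equal(dice_coefficient(a, b), 0.6)
  expect_equal(dice_coefficient(b, a), 0.6)          # symmetry
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(c(1, 0), c(0, 1)), 0)
  expect_equal(dice_coefficient(numeric(4), numeric(4)), 1)  # empty-empty
})

test_that("miou averages per-case foreground IoU", {
  m1 <- c(1, 1, 1, 1, 1, 0, 0, 0)
  m2 <- c(1, 1, 1, 0, 0, 1, 1, 0)        # |∩|=3, |∪|=7
  expect_equal(miou(list(list(pred = m1, gt = m1))), 1)
  expect_equal(miou(list(list(pred = m1, gt = m2))), 3 / 7)
  # mean contract: cases with IoUs 0.5 and 1
  c1 <- list(pred = c(1, 1, 0, 0), gt = c(1, 0, 1, 0))   # IoU 1/3
  c2 <- list(pred = c(1, 1), gt = c(1, 1))               # IoU 1
  expect_equal(miou(list(c1, c2)), (1 / 3 + 1) / 2)
  expect_error(miou(list()), "at least one")
})

test_that("classification metrics match the worked confusion table", {
  m <- classification_metrics(list(tp = 8, fp = 2, fn = 2, tn = 88))
  expect_equal(m$acc, 0.96)
  expect_equal(m$sen, 0.8)
  expect_equal(m$spe, 88 / 90)
  expect_equal(m$pre, 0.8)
  expect_equal(m$f1, 0.8)
  perfect <- classification_metrics(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_true(all(unlist(perfect) == 1))
  # undefined ratios are NA, not 0
  noneg <- classification_metrics(list(tp = 3, fp = 0, fn = 0, tn = 0))
  expect_true(is.na(noneg$spe))
})

test_that("F1 equals the harmonic mean of precision and sensitivity", {
  set.seed(31)
  for (i in 1:50) {
    cc <- list(tp = sample(1:50, 1), fp = sample(0:20, 1),
               fn = sample(0:20, 1), tn = sample(0:50, 1))
    m <- classification_metrics(cc)
    if (!is.na(m$pre) && !is.na(m$sen) && m$pre + m$sen > 0)
      expect_equal(m$f1, 2 * m$pre * m$sen / (m$pre + m$sen),
                   tolerance = 1e-12)
  }
})

test_that("classification metrics agree with a brute-force label loop", {
  set.seed(37)
  gt <- rbinom(200, 1, 0.4)
  pred <- ifelse(runif(200) < 0.85, gt, 1 - gt)
  m <- classification_metrics(confusion_counts(pred, gt))
  tp <- fp <- fn <- tn <- 0
  for (i in 1:200) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1
    if (pred[i] == 0 && gt[i] == 0) tn <- tn + 1
  }
  expect_equal(m$acc, (tp + tn) / 200)
  expect_equal(m$sen, tp / (tp + fn))
  expect_equal(m$spe, tn / (fp + tn))
  expect_equal(m$pre, tp / (tp + fp))
  expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
})

test_that("per-case IoU satisfies the Dice identity IoU = D/(2-D)", {
  set.seed(41)
  ns <- asNamespace("nodulemt")
  for (i in 1:20) {
    a <- rbinom(60, 1, 0.4)
    b <- ifelse(runif(60) < 0.8, a, 1 - a)
    d <- dice_coefficient(a, b)
    expect_equal(ns$iou_case(a, b), d / (2 - d), tolerance = 1e-9)
  }
})

test_that("aggregation formats mean ± sample sd in percent", {
  r <- aggregate_report(c(0.8, 0.8, 0.8))
  expect_equal(r$formatted, "80.00 ± 0.00")
  r2 <- aggregate_report(c(0.7, 0.9))
  expect_equal(r2$mean_pct, 80)
  expect_equal(r2$sd_pct, sd(c(70, 90)))
  expect_equal(r2$formatted, "80.00 ± 14.14")
  # grouping adds one row per level per metric
  r3 <- aggregate_report(list(dice = c(0.7, 0.9, 0.8, 0.6)),
                         group = c("A", "A", "B", "B"))
  expect_equal(nrow(r3), 3)
  expect_setequal(r3$group, c("overall", "A", "B"))
})

test_that("metrics are invariant under case permutation", {
  set.seed(43)
  cases <- lapply(1:6, function(i) {
    g <- rbinom(50, 1, 0.3)
    list(pred = ifelse(runif(50) < 0.9, g, 1 - g), gt = g)
  })
  perm <- sample(6)
  expect_equal(miou(cases), miou(cases[perm]))
  s1 <- segmentation_report(cases)$summary
  s2 <- segmentation_report(cases[perm])$summary
  expect_equal(s1$mean_pct, s2$mean_pct)
  expect_equal(s1$sd_pct, s2$sd_pct)
})
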