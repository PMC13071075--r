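# Evaluation harness: confusion counts, Dice, mean IoU, and the
# threshold-based classification metrics, with per-case values aggregated as
# mean +/- sample sd (reported in percent, as is conventional).

#' Confusion counts between binary predictions and ground truth
#'
#' Works voxel-wise (segmentation masks) or case-wise (label vectors);
#' inputs only need equal shape and binary values.
#'
#' @param pred,gt Binary arrays/vectors of equal shape.
#' @return A list with integer fields \code{tp}, \code{fp}, \code{fn},
#'   \code{tn}.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("confusion_counts: shape mismatch between pred and gt")
  p <- as.numeric(pred); g <- as.numeric(gt)
  stopifnot(all(p %in% c(0, 1)), all(g %in% c(0, 1)))
  structure(list(tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
                 fn = sum(p == 0 & g == 1), tn = sum(p == 0 & g == 0)),
            class = "confusion_counts")
}

#' Dice similarity coefficient between two binary masks
#'
#' \eqn{DICE(A,B) = 2|A \cap B| / (|A| + |B|)}. When both masks are empty the
#' coefficient is defined as 1 (perfect agreement on absence), a convention
#' needed for degenerate cases.
#'
#' @param a,b Binary masks of equal shape.
#' @return Scalar in [0, 1]; symmetric in its arguments.
#' @export
dice_coefficient <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  stopifnot(length(av) == length(bv))
  s <- sum(av) + sum(bv)
  if (s == 0) return(1)
  2 * sum(av * bv) / s
}

# Foreground intersection-over-union of one mask pair (empty-empty -> 1)
iou_case <- function(pred, gt) {
  p <- as.numeric(pred); g <- as.numeric(gt)
  u <- sum(pmax(p, g))
  if (u == 0) return(1)
  sum(p * g) / u
}

#' Mean intersection-over-union over cases
#'
#' Foreground IoU \eqn{TP_k / (TP_k + FP_k + FN_k)} computed per case and
#' averaged: the per-case reading of the mean, consistent with the identity
#' IoU = DICE / (2 - DICE) holding case-by-case. A per-class variant
#' (averaging foreground and background IoU) is available via
#' \code{per_class = TRUE}.
#'
#' @param cases List of \code{list(pred =, gt =)} binary mask pairs.
#' @param per_class Average foreground and background IoU per case first?
#' @return Scalar in [0, 1].
#' @export
miou <- function(cases, per_class = FALSE) {
  if (length(cases) < 1) stop("miou: need at least one case")
  vals <- vapply(cases, function(cs) {
    fg <- iou_case(cs$pred, cs$gt)
    if (!per_class) return(fg)
    bg <- iou_case(1 - as.numeric(cs$pred), 1 - as.numeric(cs$gt))
    (fg + bg) / 2
  }, numeric(1))
  mean(vals)
}

#' Threshold-based classification metrics from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPE = TN/(FP+TN),
#' PRE = TP/(TP+FP), F1 = 2TP/(2TP+FP+FN). Ratios with a zero denominator
#' are reported as NA rather than 0.
#'
#' @param counts A \code{confusion_counts} object or list with tp/fp/fn/tn.
#' @return Named list with acc, sen, spe, pre, f1 in [0, 1] (or NA).
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total <= 0) stop("classification_metrics: empty counts")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(acc = ratio(tp + tn, total),
       sen = ratio(tp, tp + fn),
       spe = ratio(tn, fp + tn),
       pre = ratio(tp, tp + fp),
       f1 = ratio(2 * tp, 2 * tp + fp + fn))
}

#' Aggregate per-case metric values as mean +/- sample sd, in percent
#'
#' @param values Named list (one element per metric) of numeric per-case
#'   vectors in [0, 1], or a single numeric vector.
#' @param group Optional factor of the same length stratifying cases (e.g.
#'   by center); one row per level plus an overall row is produced.
#' @return A data.frame with columns metric, group, n, mean_pct, sd_pct,
#'   formatted ("mean ± sd" to two decimals).
#' @export
aggregate_report <- function(values, group = NULL) {
  if (is.numeric(values)) values <- list(value = values)
  one <- function(v, lab) {
    m <- mean(v) * 100
    s <- if (length(v) > 1) stats::sd(v) * 100 else 0
    data.frame(metric = lab, group = "overall", n = length(v),
               mean_pct = m, sd_pct = s,
               formatted = sprintf("%.2f ± %.2f", m, s),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(values), function(nm)
    one(values[[nm]], nm)))
  if (!is.null(group)) {
    group <- as.factor(group)
    strat <- do.call(rbind, lapply(names(values), function(nm) {
      do.call(rbind, lapply(levels(group), function(lv) {
        r <- one(values[[nm]][group == lv], nm)
        r$group <- lv
        r
      }))
    }))
    out <- rbind(out, strat)
  }
  rownames(out) <- NULL
  out
}

#' Per-case segmentation report (Dice, IoU, sensitivity, precision)
#'
#' Computes voxel-level overlap metrics per prediction/ground-truth pair and
#' aggregates them with \code{\link{aggregate_report}}.
#'
#' @param cases List of \code{list(pred =, gt =)} binary mask pairs.
#' @param group Optional per-case stratification factor.
#' @return List with \code{per_case} (data.frame) and \code{summary}
#'   (aggregate report).
#' @export
segmentation_report <- function(cases, group = NULL) {
  per <- do.call(rbind, lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    cc <- confusion_counts(cs$pred, cs$gt)
    data.frame(case = i,
               dice = dice_coefficient(cs$pred, cs$gt),
               iou = iou_case(cs$pred, cs$gt),
               sen = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_,
               pre = if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_)
  }))
  vals <- list(dice = per$dice, miou = per$iou)
  if (!anyNA(per$sen)) vals$sen <- per$sen
  if (!anyNA(per$pre)) vals$pre <- per$pre
  list(per_case = per, summary = aggregate_report(vals, group))
}
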