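# Compound training objective: voxel-wise cross-entropy + soft Dice for the
# segmentation branch, case-wise cross-entropy for the classification branch,
# summed with unit task weights. These functions operate on plain probability
# arrays and are the reference the (fused, logit-space) training losses are
# tested against.

.norm_seg_probs <- function(seg_probs) {
  d <- dim(seg_probs)
  if (length(d) == 4L) dim(seg_probs) <- c(d[1:3], d[4], 1L)
  d <- dim(seg_probs)
  stopifnot(d[4] == 2L)
  seg_probs
}

.norm_mask <- function(gt, d) {
  g <- as.numeric(gt)
  stopifnot(all(g %in% c(0, 1)))
  array(g, c(prod(d[1:3]), d[5]))
}

#' Voxel-wise segmentation cross-entropy
#'
#' Mean over all voxels of the negative log-probability of the true class,
#' computed per sample and averaged over the batch. Probabilities are floored
#' at \code{log_floor} inside the log, since the loss is undefined at an
#' exact zero.
#'
#' @param seg_probs Array of per-voxel class probabilities, dim
#'   (d1, d2, d3, 2[, N]); channel 1 = background, channel 2 = nodule.
#' @param gt Binary mask, dim (d1, d2, d3[, N]).
#' @param log_floor Floor applied inside the logarithm (default 1e-12).
#' @return Non-negative scalar.
#' @export
ce_seg_loss <- function(seg_probs, gt, log_floor = 1e-12) {
  p <- .norm_seg_probs(seg_probs)
  d <- dim(p)
  V <- prod(d[1:3])
  parr <- array(p, c(V, 2, d[5]))
  y1 <- .norm_mask(gt, d)
  ptrue <- ifelse(y1 > 0.5, array(parr[, 2, ], c(V, d[5])),
                  array(parr[, 1, ], c(V, d[5])))
  mean(colMeans(-log(pmax(ptrue, log_floor))))
}

#' Soft Dice loss on the nodule channel
#'
#' \deqn{L_{Dice} = 1 - \frac{2\sum_i p_{i,1} y_{i,1} + \epsilon}
#'   {\sum_i p_{i,1} + \sum_i y_{i,1} + \epsilon}}
#' computed per sample on the foreground (nodule) probability channel and
#' averaged over the batch. The smoothing constant \eqn{\epsilon}
#' (default 1e-5) keeps the ratio and its gradient finite when both the
#' prediction and the mask are empty.
#'
#' @inheritParams ce_seg_loss
#' @param eps Smoothing constant (default 1e-5).
#' @return Scalar in [0, 1].
#' @export
dice_loss <- function(seg_probs, gt, eps = 1e-5) {
  p <- .norm_seg_probs(seg_probs)
  d <- dim(p)
  V <- prod(d[1:3])
  p1 <- array(array(p, c(V, 2, d[5]))[, 2, ], c(V, d[5]))
  y1 <- .norm_mask(gt, d)
  per <- 1 - (2 * colSums(p1 * y1) + eps) / (colSums(p1) + colSums(y1) + eps)
  mean(per)
}

#' Classification cross-entropy
#'
#' Mean over the batch of the negative log-probability of the true class.
#'
#' @param cls_probs Matrix (2, B) or vector of length 2: per-sample class
#'   probabilities (benign, malignant).
#' @param labels Integer vector of 0 (benign) / 1 (malignant), length B.
#' @param log_floor Floor inside the logarithm.
#' @return Non-negative scalar.
#' @export
cls_loss <- function(cls_probs, labels, log_floor = 1e-12) {
  p <- cls_probs
  if (is.null(dim(p))) p <- matrix(p, 2, 1)
  stopifnot(nrow(p) == 2, ncol(p) == length(labels))
  idx <- cbind(as.integer(labels) + 1L, seq_len(ncol(p)))
  mean(-log(pmax(p[idx], log_floor)))
}

#' Compound multi-task loss
#'
#' Combines the segmentation loss (cross-entropy + Dice) and classification
#' loss with unit task weights:
#' \eqn{L_{total} = L_{seg} + L_{cls} = (L_{CE} + L_{Dice}) + L_{cls}}.
#'
#' @inheritParams ce_seg_loss
#' @inheritParams cls_loss
#' @param eps Dice smoothing constant.
#' @return A \code{loss_breakdown}: list with \code{l_total}, \code{l_seg},
#'   \code{l_ce}, \code{l_dice}, \code{l_cls}.
#' @export
total_loss <- function(seg_probs, gt, cls_probs, labels, eps = 1e-5) {
  l_ce <- ce_seg_loss(seg_probs, gt)
  l_dice <- dice_loss(seg_probs, gt, eps)
  l_cls <- cls_loss(cls_probs, labels)
  loss_breakdown(l_ce, l_dice, l_cls)
}

#' Assemble a loss breakdown from its components
#' @param l_ce,l_dice,l_cls Component losses.
#' @return A \code{loss_breakdown} list.
#' @export
loss_breakdown <- function(l_ce, l_dice, l_cls) {
  l_seg <- l_ce + l_dice
  structure(list(l_total = l_seg + l_cls, l_seg = l_seg, l_ce = l_ce,
                 l_dice = l_dice, l_cls = l_cls),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total %.4f = seg %.4f (ce %.4f + dice %.4f) + cls %.4f\n",
    x$l_total, x$l_seg, x$l_ce, x$l_dice, x$l_cls))
  invisible(x)
}
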