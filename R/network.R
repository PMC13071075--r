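# Model assembly: 3-D residual (18-layer style) encoder, decoder with
# attention-gated skips and multi-scale convolution, dual spatial attention
# in the two deepest decoder stages, and a channel-attention-gated
# classification branch tapping encoder stages 3-4 plus the first fused
# decoder feature.

#' Network configuration
#'
#' @param in_channels Input channels (CT intensity only: 1).
#' @param stage_channels Encoder stage widths, length 4 (default
#'   c(64, 128, 256, 512), the standard 18-layer residual ladder). Reduced
#'   widths give a desk-scale model.
#' @param active_blocks Character subset of c("CA", "GSA", "DSA", "MSConv");
#'   inactive blocks become identity (ablation switches). Default: all.
#' @param with_classifier Build the classification branch? \code{FALSE}
#'   yields the pure segmentation topology.
#' @param patch_size Input cube edge; must be a multiple of 32 (the encoder
#'   downsamples by 32).
#' @param dsa_kernel Spatial-attention map kernel (odd, default 7).
#' @param ca_reduction Channel-attention bottleneck ratio (default 4).
#' @param msconv_dilation Dilation of the multi-scale branches (default 1).
#' @param cls_hidden Width of the classification head's hidden layer
#'   (default \code{stage_channels[2]}).
#' @param seed Seed for weight initialization.
#' @return A \code{network_config} list.
#' @export
network_config <- function(in_channels = 1L,
                           stage_channels = c(64L, 128L, 256L, 512L),
                           active_blocks = c("CA", "GSA", "DSA", "MSConv"),
                           with_classifier = TRUE,
                           patch_size = 64L,
                           dsa_kernel = 7L,
                           ca_reduction = 4L,
                           msconv_dilation = 1L,
                           cls_hidden = NULL,
                           seed = 1L) {
  stopifnot(length(stage_channels) == 4, all(stage_channels >= 2),
            patch_size %% 32L == 0L,
            all(active_blocks %in% c("CA", "GSA", "DSA", "MSConv")))
  if (is.null(cls_hidden)) cls_hidden <- stage_channels[2]
  structure(list(in_channels = as.integer(in_channels),
                 seg_classes = 2L, cls_classes = 2L,
                 stage_channels = as.integer(stage_channels),
                 active_blocks = active_blocks,
                 with_classifier = isTRUE(with_classifier),
                 patch_size = as.integer(patch_size),
                 dsa_kernel = as.integer(dsa_kernel),
                 ca_reduction = as.integer(ca_reduction),
                 msconv_dilation = as.integer(msconv_dilation),
                 cls_hidden = as.integer(cls_hidden),
                 seed = as.integer(seed)),
            class = "network_config")
}

# Basic residual unit: conv3-GN-ReLU-conv3-GN (+ projection shortcut) -> ReLU
basic_block <- function(c_in, c_out, stride = 1L) {
  conv1 <- layer_conv3d(c_in, c_out, 3L, stride = stride)
  gn1 <- layer_group_norm(c_out)
  conv2 <- layer_conv3d(c_out, c_out, 3L)
  gn2 <- layer_group_norm(c_out)
  layers <- list(conv1 = conv1, gn1 = gn1, conv2 = conv2, gn2 = gn2)
  if (stride != 1L || c_in != c_out) {
    sc <- layer_conv3d(c_in, c_out, 1L, stride = stride)
    scn <- layer_group_norm(c_out)
    layers$sc <- sc; layers$scn <- scn
    short <- function(x) scn$fwd(sc$fwd(x))
  } else short <- function(x) x
  new_layer(
    fwd = function(x) {
      h <- gn2$fwd(conv2$fwd(ag_relu(gn1$fwd(conv1$fwd(x)))))
      ag_relu(ag_add(h, short(x)))
    },
    params = collect_params(layers)
  )
}

res_stage <- function(c_in, c_out, stride) {
  b1 <- basic_block(c_in, c_out, stride)
  b2 <- basic_block(c_out, c_out, 1L)
  new_layer(fwd = function(x) b2$fwd(b1$fwd(x)),
            params = collect_params(list(b1 = b1, b2 = b2)))
}

#' Build the multi-task model
#'
#' Encoder: 7-cubed stride-2 stem + stride-2 max pooling, then four residual
#' stages giving hierarchical maps at 1/4, 1/8, 1/16 and 1/32 of the input.
#' Decoder: three trilinear-upsample + concat-fusion stages (each skip gated
#' by GSA when active, each fused feature refined by MSConv when active, and
#' DSA applied in the two deepest decoder stages), then an upsampling head to
#' full resolution with 2 segmentation logits per voxel. Classification
#' branch: encoder stages 3 and 4 plus the first fused decoder feature, each
#' gated by its own CA, globally average-pooled, concatenated, and mapped by
#' a hidden fully connected layer to 2 logits. Weights are Kaiming-
#' initialized from \code{config$seed}.
#'
#' @param config A \code{\link{network_config}}.
#' @return A \code{nodule_model}: list with \code{fwd}, \code{params},
#'   \code{config}, \code{n_parameters}.
#' @export
build_model <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  ch <- config$stage_channels
  act <- function(b) b %in% config$active_blocks
  with_seed(config$seed, {
    stem <- layer_cnr(config$in_channels, ch[1], k = 7L, stride = 2L)
    enc <- list(res_stage(ch[1], ch[1], 1L),
                res_stage(ch[1], ch[2], 2L),
                res_stage(ch[2], ch[3], 2L),
                res_stage(ch[3], ch[4], 2L))
    gsa <- lapply(1:3, function(i)
      if (act("GSA")) gsa_block(ch[i]) else identity_layer())
    fuse <- lapply(1:3, function(i) {
      below <- if (i == 3L) ch[4] else ch[i + 1]
      layer_cnr(ch[i] + below, ch[i], k = 3L)
    })
    msc <- lapply(1:3, function(i)
      if (act("MSConv")) msconv_block(ch[i], ch[i],
                                      dilation = config$msconv_dilation)
      else identity_layer())
    dsa <- lapply(2:3, function(i)
      if (act("DSA")) dsa_block(ch[i], config$dsa_kernel)
      else identity_layer())     # decoder stages 1 and 2 (deepest first)
    head_c <- max(2L, ch[1] %/% 2L)
    head_conv <- layer_cnr(ch[1], head_c, k = 3L)
    head_out <- layer_conv3d(head_c, config$seg_classes, 1L)
    layers <- list(stem = stem, e1 = enc[[1]], e2 = enc[[2]], e3 = enc[[3]],
                   e4 = enc[[4]], gsa1 = gsa[[1]], gsa2 = gsa[[2]],
                   gsa3 = gsa[[3]], fuse1 = fuse[[1]], fuse2 = fuse[[2]],
                   fuse3 = fuse[[3]], msc1 = msc[[1]], msc2 = msc[[2]],
                   msc3 = msc[[3]], dsa2 = dsa[[1]], dsa3 = dsa[[2]],
                   head_conv = head_conv, head_out = head_out)
    if (config$with_classifier) {
      ca_streams <- lapply(c(ch[3], ch[4], ch[3]), function(C)
        if (act("CA")) ca_block(C, config$ca_reduction) else identity_layer())
      cls_fc1 <- layer_linear(ch[3] + ch[4] + ch[3], config$cls_hidden)
      cls_fc2 <- layer_linear(config$cls_hidden, config$cls_classes)
      layers <- c(layers, list(ca_e3 = ca_streams[[1]],
                               ca_e4 = ca_streams[[2]],
                               ca_ffm = ca_streams[[3]],
                               cls_fc1 = cls_fc1, cls_fc2 = cls_fc2))
    }
  })
  params <- collect_params(layers)

  fwd <- function(x) {
    x <- as_vt(x)
    if (length(dim(x$value)) != 5L || dim(x$value)[4] != config$in_channels)
      stop("forward: expected input of dim (d, d, d, ",
           config$in_channels, ", N)")
    s <- layers$stem$fwd(x)
    p <- ag_maxpool3d(s, 3L, 2L, 1L)
    e1 <- layers$e1$fwd(p)
    e2 <- layers$e2$fwd(e1)
    e3 <- layers$e3$fwd(e2)
    e4 <- layers$e4$fwd(e3)
    up_to <- function(t, ref) ag_upsample(t, dim(ref$value))
    # decoder stage 1 (deepest): fuse with e3; its fused map is "ffm1"
    ffm1 <- layers$fuse3$fwd(ag_concat_ch(list(layers$gsa3$fwd(e3),
                                               up_to(e4, e3))))
    t3 <- layers$dsa3$fwd(layers$msc3$fwd(ffm1))
    # decoder stage 2: fuse with e2
    f2 <- layers$fuse2$fwd(ag_concat_ch(list(layers$gsa2$fwd(e2),
                                             up_to(t3, e2))))
    t2 <- layers$dsa2$fwd(layers$msc2$fwd(f2))
    # decoder stage 3: fuse with e1 (no DSA)
    f1 <- layers$fuse1$fwd(ag_concat_ch(list(layers$gsa1$fwd(e1),
                                             up_to(t2, e1))))
    t1 <- layers$msc1$fwd(f1)
    # head to full resolution
    dfull <- dim(x$value)
    dhalf <- c(dfull[1:3] %/% 2L, dim(t1$value)[4], dfull[5])
    h <- layers$head_conv$fwd(ag_upsample(t1, dhalf))
    seg <- layers$head_out$fwd(
      ag_upsample(h, c(dfull[1:3], dim(h$value)[4], dfull[5])))
    out <- list(seg = seg, ffm1 = ffm1)
    if (config$with_classifier) {
      feats <- ag_rbind(list(ag_gap(layers$ca_e3$fwd(e3)),
                             ag_gap(layers$ca_e4$fwd(e4)),
                             ag_gap(layers$ca_ffm$fwd(ffm1))))
      out$cls <- layers$cls_fc2$fwd(ag_relu(layers$cls_fc1$fwd(feats)))
    }
    out
  }

  structure(list(fwd = fwd, params = params, config = config,
                 n_parameters = n_params(params)),
            class = "nodule_model")
}

#' @export
print.nodule_model <- function(x, ...) {
  cat(sprintf("nodule_model: stages %s, blocks {%s}%s, %d parameters\n",
              paste(x$config$stage_channels, collapse = "/"),
              paste(x$config$active_blocks, collapse = ","),
              if (x$config$with_classifier) " + classifier" else "",
              x$n_parameters))
  invisible(x)
}

#' Count trainable parameters
#' @param model A \code{nodule_model}.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) model$n_parameters

#' Run the model on a batch of patches (inference)
#'
#' @param model A \code{nodule_model}.
#' @param images Numeric array (d, d, d, N) or (d, d, d, 1, N) of normalized
#'   intensities.
#' @return List with \code{seg_logits} (d, d, d, 2, N) and (when the model
#'   has a classifier) \code{cls_logits} (2, N) and \code{cls_probs} (2, N).
#' @export
model_forward <- function(model, images) {
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d, 1L, 1L)
  else if (length(d) == 4L) dim(images) <- c(d[1:3], 1L, d[4])
  out <- ag_no_grad(model$fwd(vt(images)))
  res <- list(seg_logits = out$seg$value)
  if (!is.null(out$cls)) {
    z <- out$cls$value
    ez <- exp(sweep(z, 2, apply(z, 2, max)))
    res$cls_logits <- z
    res$cls_probs <- sweep(ez, 2, colSums(ez), "/")
  }
  res
}

#' Voxel-wise class probabilities and argmax mask from segmentation logits
#' @param seg_logits Array (d, d, d, 2[, N]).
#' @return List with \code{probs} (same dim) and binary \code{mask}
#'   (d, d, d[, N]) by argmax.
#' @export
seg_predictions <- function(seg_logits) {
  d <- dim(seg_logits)
  if (length(d) == 4L) dim(seg_logits) <- c(d[1:3], d[4], 1L)
  d <- dim(seg_logits)
  V <- prod(d[1:3])
  z <- array(seg_logits, c(V, 2, d[5]))
  p1 <- 1 / (1 + exp(z[, 1, ] - z[, 2, ]))
  probs <- array(0, d)
  probs[, , , 2, ] <- p1
  probs[, , , 1, ] <- 1 - p1
  mask <- array(as.numeric(p1 > 0.5), c(d[1:3], d[5]))
  list(probs = probs, mask = mask)
}

#' Save model weights and configuration to a single-file checkpoint
#' @param model A \code{nodule_model}.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config,
               values = lapply(model$params, function(p) p$value)),
          path)
  invisible(path)
}

#' Load a checkpoint written by \code{\link{save_checkpoint}}
#' @param path Checkpoint file.
#' @return A \code{nodule_model} with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  stopifnot(identical(names(model$params), names(ck$values)))
  for (nm in names(ck$values)) model$params[[nm]]$value <- ck$values[[nm]]
  model
}
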