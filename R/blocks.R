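# Architectural primitives: adaptive group-number rule, multi-scale grouped
# convolution (MSConv), global semantic attention (GSA), dual spatial
# attention (DSA) and squeeze-excite channel attention (CA).

#' Adaptive group number for grouped convolution
#'
#' Returns the largest integer \code{g} such that
#' \code{g <= min(floor(c_in / 2), c_out)} and \code{g} divides \code{c_out}.
#' When \code{floor(c_in / 2)} is zero (single input channel) the result is 1,
#' the always-admissible group count.
#'
#' @param c_in,c_out Input and output channel counts (positive integers).
#' @return Integer group count.
#' @examples
#' group_number(64, 64)  # 32
#' group_number(32, 48)  # 16
#' group_number(3, 8)    # 1
#' @export
group_number <- function(c_in, c_out) {
  stopifnot(c_in >= 1, c_out >= 1)
  cap <- min(c_in %/% 2L, c_out)
  if (cap < 1L) return(1L)
  for (g in seq(cap, 1L)) if (c_out %% g == 0L) return(as.integer(g))
  1L
}

#' Multi-scale grouped convolution block specification
#'
#' @param c_in,c_out Channel counts.
#' @param dilation Dilation rate applied to the three multi-scale branches
#'   (default 1, i.e. literal kernel sizes 1/3/5).
#' @return A list with the branch kernel sizes, the residual kernel and the
#'   shared group number.
#' @details The group count starts from \code{\link{group_number}} and is
#'   additionally required to divide \code{c_in} — a realizability
#'   constraint of grouped convolution (each group needs a whole number of
#'   input channels). In the decoder the block is used with
#'   \code{c_in == c_out}, where the two rules coincide.
#' @export
msconv_spec <- function(c_in, c_out, dilation = 1L) {
  g <- group_number(c_in, c_out)
  while (g > 1L && c_in %% g != 0L) {
    g <- g - 1L
    while (g > 1L && c_out %% g != 0L) g <- g - 1L
  }
  structure(list(c_in = as.integer(c_in), c_out = as.integer(c_out),
                 kernel_sizes = c(1L, 3L, 5L), residual_kernel = 3L,
                 groups = g, dilation = as.integer(dilation)),
            class = "msconv_spec")
}

#' Multi-scale grouped convolution (MSConv) block
#'
#' Four parallel grouped convolutions over the same input — kernel sizes
#' 1, 3 and 5 plus a residual 3-cubed branch — summed element-wise:
#' \deqn{Y = Conv_{res}^{(g)}(X) + \sum_{k \in \{1,3,5\}} Conv_k^{(g)}(X)}
#' All branches share the group number from \code{\link{group_number}} and
#' use "same" spatial padding so the sum is well defined.
#'
#' @param c_in,c_out Channel counts.
#' @param dilation Dilation for the multi-scale branches (1 = plain kernels).
#' @return A block: list with \code{$fwd} (vtensor -> vtensor) and
#'   \code{$params}.
#' @export
msconv_block <- function(c_in, c_out, dilation = 1L) {
  spec <- msconv_spec(c_in, c_out, dilation)
  g <- spec$groups
  br <- lapply(spec$kernel_sizes, function(k)
    layer_conv3d(c_in, c_out, k = k, groups = g,
                 dilation = if (k > 1L) spec$dilation else 1L))
  res <- layer_conv3d(c_in, c_out, k = spec$residual_kernel, groups = g)
  layers <- c(stats::setNames(br, paste0("k", spec$kernel_sizes)),
              list(res = res))
  blk <- new_layer(
    fwd = function(x) {
      y <- res$fwd(x)
      for (b in br) y <- ag_add(y, b$fwd(x))
      y
    },
    params = collect_params(layers)
  )
  blk$spec <- spec
  blk
}

#' Global semantic attention (GSA) block
#'
#' Gates skip-connection features. Two 1-cubed convolutional projections
#' (each followed by group norm and ReLU) produce two response maps; each map
#' is passed through a sigmoid and reduced to a channel descriptor — by
#' global average pooling for the first and global max pooling for the
#' second. The input is reweighted channel-wise by both descriptors
#' (multiplicative gating) and refined by a 3-cubed conv + norm + ReLU.
#' Output shape equals input shape.
#'
#' @param channels Feature channels C.
#' @return A block (\code{$fwd}, \code{$params}); \code{$descriptors(x)}
#'   returns the two channel descriptors for inspection.
#' @export
gsa_block <- function(channels) {
  proj_avg <- layer_cnr(channels, channels, k = 1L)
  proj_max <- layer_cnr(channels, channels, k = 1L)
  refine <- layer_cnr(channels, channels, k = 3L)
  descriptors <- function(x) {
    x <- as_vt(x)
    list(avg = ag_gap(ag_sigmoid(proj_avg$fwd(x))),
         max = ag_gmp(ag_sigmoid(proj_max$fwd(x))))
  }
  blk <- new_layer(
    fwd = function(x) {
      x <- as_vt(x)
      d <- descriptors(x)
      refine$fwd(ag_scale_channels(ag_scale_channels(x, d$avg), d$max))
    },
    params = collect_params(list(proj_avg = proj_avg, proj_max = proj_max,
                                 refine = refine))
  )
  blk$descriptors <- descriptors
  blk
}

#' Dual spatial attention (DSA) block
#'
#' Channel-wise average pooling and channel-wise max pooling each give a
#' one-channel spatial map; each map is convolved (odd \code{spatial_kernel})
#' and squashed by a sigmoid into a spatial weighting map. The two rescaled
#' copies of the input are combined by element-wise sum, so consensus-based
#' and peak-based spatial cues both contribute. Output shape equals input.
#'
#' @param channels Feature channels (unused by the pooling itself; kept for
#'   interface symmetry and validation).
#' @param spatial_kernel Odd kernel size of the map convolution (default 7).
#' @return A block; \code{$maps(x)} exposes the two sigmoid weighting maps.
#' @export
dsa_block <- function(channels, spatial_kernel = 7L) {
  stopifnot(spatial_kernel %% 2L == 1L)
  conv_avg <- layer_conv3d(1L, 1L, k = spatial_kernel)
  conv_max <- layer_conv3d(1L, 1L, k = spatial_kernel)
  maps <- function(x) {
    x <- as_vt(x)
    list(avg = ag_sigmoid(conv_avg$fwd(ag_chan_mean(x))),
         max = ag_sigmoid(conv_max$fwd(ag_chan_max(x))))
  }
  blk <- new_layer(
    fwd = function(x) {
      x <- as_vt(x)
      m <- maps(x)
      ag_add(ag_scale_spatial(x, m$avg), ag_scale_spatial(x, m$max))
    },
    params = collect_params(list(conv_avg = conv_avg, conv_max = conv_max))
  )
  blk$maps <- maps
  blk
}

#' Channel attention (CA) block, squeeze-excite form
#'
#' Global average pooling, a bottleneck fully connected layer of width
#' \code{max(1, channels / reduction)} with ReLU, an expansion back to
#' \code{channels}, and a sigmoid produce channel weights in (0,1) that
#' rescale the input channel-wise.
#'
#' @param channels Feature channels C.
#' @param reduction Bottleneck reduction ratio (default 4).
#' @return A block; \code{$weights(x)} exposes the channel weights.
#' @export
ca_block <- function(channels, reduction = 4L) {
  hidden <- max(1L, channels %/% reduction)
  fc1 <- layer_linear(channels, hidden)
  fc2 <- layer_linear(hidden, channels)
  weights <- function(x) {
    x <- as_vt(x)
    ag_sigmoid(fc2$fwd(ag_relu(fc1$fwd(ag_gap(x)))))
  }
  blk <- new_layer(
    fwd = function(x) {
      x <- as_vt(x)
      ag_scale_channels(x, weights(x))
    },
    params = collect_params(list(fc1 = fc1, fc2 = fc2))
  )
  blk$weights <- weights
  blk
}

#' Run a block on a plain numeric array
#'
#' Convenience wrapper: wraps the array, runs the block's forward pass
#' without recording gradients, and returns the value array.
#'
#' @param block A block built by one of the \code{*_block} constructors.
#' @param x Numeric array, dim (d1, d2, d3, C, N); a 4-D array is treated as
#'   a single sample.
#' @return Numeric array of the block output.
#' @export
block_forward <- function(block, x) {
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  ag_no_grad(vt_value(block$fwd(vt(x))))
}
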