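# Reverse-mode automatic differentiation over dense arrays.
#
# A `vtensor` is an environment holding a numeric array (`value`), an
# accumulated gradient (`grad`), the nodes it was computed from (`parents`)
# and a closure (`bwd`) mapping the incoming gradient to one gradient per
# parent. Feature maps use dim c(d1, d2, d3, C, N); vectors/matrices are used
# where noted. Graph recording can be suspended (eval mode) with ag_no_grad().

.ag <- new.env(parent = emptyenv())
.ag$grad_enabled <- TRUE
.ag$id <- 0L

#' Create an autograd tensor
#'
#' Wraps a numeric array as a node of the automatic-differentiation graph.
#' Leaf nodes with `requires_grad = TRUE` are trainable parameters.
#'
#' @param value Numeric array (any dim).
#' @param requires_grad Should gradients be accumulated into this node?
#' @return A `vtensor` object.
#' @keywords internal
vt <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$parents <- list()
  e$bwd <- NULL
  .ag$id <- .ag$id + 1L
  e$id <- .ag$id
  class(e) <- "vtensor"
  e
}

as_vt <- function(x) if (inherits(x, "vtensor")) x else vt(x)

vt_value <- function(x) if (inherits(x, "vtensor")) x$value else x

needs_grad <- function(x) {
  inherits(x, "vtensor") && (x$requires_grad || length(x$parents) > 0L)
}

#' Evaluate an expression without recording the autograd graph
#' @param expr Expression to evaluate.
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  force(expr)
}

# Build an op node: `value` already computed, `inputs` the vtensor inputs,
# `bwd` function(grad) returning a list of gradients aligned with `inputs`
# (NULL entries allowed for inputs that need no gradient).
ag_node <- function(value, inputs, bwd) {
  out <- vt(value)
  if (.ag$grad_enabled && any(vapply(inputs, needs_grad, logical(1)))) {
    out$parents <- inputs
    out$bwd <- bwd
  }
  out
}

#' Run backpropagation from a scalar loss node
#'
#' Topologically sorts the recorded graph and accumulates gradients into
#' every reachable node with `requires_grad = TRUE`.
#'
#' @param root A scalar `vtensor`.
#' @param seed Gradient seeded at the root (default 1).
#' @keywords internal
ag_backward <- function(root, seed = 1) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  grads <- new.env(parent = emptyenv())
  assign(as.character(root$id), seed, envir = grads)
  for (node in rev(order)) {
    g <- get0(as.character(node$id), envir = grads)
    if (is.null(g)) next
    if (node$requires_grad) {
      node$grad <- if (is.null(node$grad)) g else node$grad + g
    }
    if (is.null(node$bwd)) next
    pg <- node$bwd(g)
    for (i in seq_along(node$parents)) {
      p <- node$parents[[i]]
      if (is.null(pg[[i]])) next
      k <- as.character(p$id)
      old <- get0(k, envir = grads)
      assign(k, if (is.null(old)) pg[[i]] else old + pg[[i]], envir = grads)
    }
  }
  invisible(root)
}

# ---- elementwise and arithmetic ops ----------------------------------------

ag_add <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_relu <- function(x) {
  x <- as_vt(x)
  keep <- x$value > 0
  ag_node(x$value * keep, list(x), function(g) list(g * keep))
}

ag_sigmoid <- function(x) {
  x <- as_vt(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

# ---- convolution, pooling, resize ------------------------------------------

#' Grouped 3D convolution (autograd op)
#'
#' @param x Input `vtensor`, dim (d1, d2, d3, C_in, N).
#' @param w Weights, dim (k, k, k, C_in/groups, C_out).
#' @param b Bias, length C_out.
#' @param stride,pad,dilation Convolution geometry (isotropic).
#' @param groups Number of channel groups; must divide C_in and C_out.
#' @keywords internal
ag_conv3d <- function(x, w, b, stride = 1L, pad = 0L, dilation = 1L,
                      groups = 1L) {
  x <- as_vt(x); w <- as_vt(w); b <- as_vt(b)
  wd <- dim(w$value)
  k <- wd[1]; c_out <- wd[5]
  xv <- x$value; wv <- w$value
  xdim <- as.integer(dim(xv))
  stopifnot(xdim[4] %% groups == 0, c_out %% groups == 0,
            xdim[4] %/% groups == wd[4])
  y <- cpp_conv3d_forward(xv, xdim, wv, b$value,
                          as.integer(k), as.integer(stride), as.integer(pad),
                          as.integer(dilation), as.integer(groups),
                          as.integer(c_out))
  ag_node(y, list(x, w, b), function(g) {
    bk <- cpp_conv3d_backward(xv, xdim, wv, g,
                              as.integer(k), as.integer(stride),
                              as.integer(pad), as.integer(dilation),
                              as.integer(groups), as.integer(c_out))
    list(bk$dx, bk$dw, bk$db)
  })
}

ag_maxpool3d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  x <- as_vt(x)
  res <- cpp_maxpool3d(x$value, as.integer(dim(x$value)),
                       as.integer(k), as.integer(stride), as.integer(pad))
  xd <- dim(x$value)
  ag_node(res$y, list(x), function(g) {
    dx <- numeric(prod(xd))
    gv <- as.numeric(g)
    # overlapping windows can select the same input voxel: group-accumulate
    acc <- rowsum(gv, group = res$argmax)
    dx[as.integer(rownames(acc))] <- acc
    dim(dx) <- xd
    list(dx)
  })
}

ag_upsample <- function(x, odim) {
  x <- as_vt(x)
  xd <- as.integer(dim(x$value))
  od <- as.integer(odim)
  y <- cpp_trilinear_resize(x$value, xd, od)
  ag_node(y, list(x), function(g) {
    list(cpp_trilinear_resize_backward(as.numeric(g), xd, od))
  })
}

# ---- normalization ----------------------------------------------------------

#' Group normalization (autograd op)
#'
#' Normalizes over (spatial x channels-in-group) per sample, then applies a
#' per-channel affine transform.
#' @param x Input, dim (d1, d2, d3, C, N).
#' @param gamma,beta Per-channel scale and shift (length C).
#' @param groups Number of channel groups (must divide C).
#' @keywords internal
ag_group_norm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- as_vt(x); gamma <- as_vt(gamma); beta <- as_vt(beta)
  d <- dim(x$value)
  V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  stopifnot(C %% groups == 0)
  cg <- C %/% groups
  M <- V * cg                       # elements per normalization group
  xg <- array(x$value, c(M, groups, N))
  mu <- colMeans(xg)                              # (groups, N)
  va <- colMeans(xg^2) - mu^2
  sd_inv <- 1 / sqrt(va + eps)
  xhat <- (xg - rep(mu, each = M)) * rep(sd_inv, each = M)
  gam_full <- rep(rep(gamma$value, each = V), times = N)   # aligned with x
  bet_full <- rep(rep(beta$value, each = V), times = N)
  y <- array(as.numeric(xhat) * gam_full + bet_full, d)
  ag_node(y, list(x, gamma, beta), function(g) {
    gv <- as.numeric(g)
    xh <- as.numeric(xhat)
    dgamma <- rowSums(matrix(colSums(matrix(gv * xh, nrow = V)), nrow = C))
    dbeta <- rowSums(matrix(colSums(matrix(gv, nrow = V)), nrow = C))
    dxhat <- array(gv * gam_full, c(M, groups, N))
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * array(xh, c(M, groups, N)))
    dx <- rep(sd_inv, each = M) *
      (dxhat - rep(m1, each = M) - array(xh, c(M, groups, N)) * rep(m2, each = M))
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# ---- pooling to descriptors and channel reductions -------------------------

# Global average pool: (d1,d2,d3,C,N) -> (C,N)
ag_gap <- function(x) {
  x <- as_vt(x)
  d <- dim(x$value)
  V <- prod(d[1:3])
  m <- array(x$value, c(V, d[4], d[5]))
  y <- matrix(colMeans(m), d[4], d[5])
  ag_node(y, list(x), function(g) {
    dx <- array(rep(as.numeric(g) / V, each = V), d)
    list(dx)
  })
}

# Global max pool: (d1,d2,d3,C,N) -> (C,N)
ag_gmp <- function(x) {
  x <- as_vt(x)
  d <- dim(x$value)
  V <- prod(d[1:3])
  m <- array(x$value, c(V, d[4] * d[5]))
  idx <- max.col(t(m), ties.method = "first")   # argmax per (c,n)
  y <- matrix(m[cbind(idx, seq_along(idx))], d[4], d[5])
  ag_node(y, list(x), function(g) {
    dx <- array(0, c(V, d[4] * d[5]))
    dx[cbind(idx, seq_along(idx))] <- as.numeric(g)
    dim(dx) <- d
    list(dx)
  })
}

# Channel-wise mean: (d1,d2,d3,C,N) -> (d1,d2,d3,1,N)
ag_chan_mean <- function(x) {
  x <- as_vt(x)
  d <- dim(x$value)
  V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  m <- array(x$value, c(V, C, N))
  y <- array(apply(m, 3, rowMeans), c(d[1:3], 1, N))
  ag_node(y, list(x), function(g) {
    gv <- array(as.numeric(g) / C, c(V, N))
    dx <- array(0, c(V, C, N))
    for (ci in seq_len(C)) dx[, ci, ] <- gv
    dim(dx) <- d
    list(dx)
  })
}

# Channel-wise max: (d1,d2,d3,C,N) -> (d1,d2,d3,1,N)
ag_chan_max <- function(x) {
  x <- as_vt(x)
  d <- dim(x$value)
  V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  m <- aperm(array(x$value, c(V, C, N)), c(2, 1, 3))  # (C, V, N)
  dim(m) <- c(C, V * N)
  idx <- max.col(t(m), ties.method = "first")         # argmax channel
  y <- array(m[cbind(idx, seq_along(idx))], c(d[1:3], 1, N))
  ag_node(y, list(x), function(g) {
    dx <- array(0, c(C, V * N))
    dx[cbind(idx, seq_along(idx))] <- as.numeric(g)
    dim(dx) <- c(C, V, N)
    dx <- aperm(dx, c(2, 1, 3))
    dim(dx) <- d
    list(dx)
  })
}

# Scale each channel of x by s: x (d1,d2,d3,C,N), s (C,N)
ag_scale_channels <- function(x, s) {
  x <- as_vt(x); s <- as_vt(s)
  d <- dim(x$value)
  V <- prod(d[1:3])
  sfull <- rep(as.numeric(s$value), each = V)
  xv <- x$value
  y <- array(as.numeric(xv) * sfull, d)
  ag_node(y, list(x, s), function(g) {
    gv <- as.numeric(g)
    dx <- array(gv * sfull, d)
    ds <- matrix(colSums(matrix(gv * as.numeric(xv), nrow = V)),
                 d[4], d[5])
    list(dx, ds)
  })
}

# Scale all channels of x by a one-channel spatial map m (d1,d2,d3,1,N)
ag_scale_spatial <- function(x, m) {
  x <- as_vt(x); m <- as_vt(m)
  d <- dim(x$value)
  V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  mm <- array(m$value, c(V, N))
  xv <- array(x$value, c(V, C, N))
  y <- xv
  for (ci in seq_len(C)) y[, ci, ] <- y[, ci, ] * mm
  dim(y) <- d
  ag_node(y, list(x, m), function(g) {
    gv <- array(as.numeric(g), c(V, C, N))
    dx <- gv
    dm <- array(0, c(V, N))
    for (ci in seq_len(C)) {
      dx[, ci, ] <- gv[, ci, ] * mm
      dm <- dm + gv[, ci, ] * xv[, ci, ]
    }
    dim(dx) <- d
    dim(dm) <- c(d[1:3], 1, N)
    list(dx, dm)
  })
}

# Concatenate along the channel axis (dim 4)
ag_concat_ch <- function(xs) {
  xs <- lapply(xs, as_vt)
  dims <- lapply(xs, function(t) dim(t$value))
  Cs <- vapply(dims, function(d) d[4], numeric(1))
  d0 <- dims[[1]]
  out <- array(0, c(d0[1:3], sum(Cs), d0[5]))
  off <- 0
  for (i in seq_along(xs)) {
    out[, , , off + seq_len(Cs[i]), ] <- xs[[i]]$value
    off <- off + Cs[i]
  }
  ag_node(out, xs, function(g) {
    res <- vector("list", length(xs))
    off <- 0
    for (i in seq_along(xs)) {
      res[[i]] <- g[, , , off + seq_len(Cs[i]), , drop = FALSE]
      dim(res[[i]]) <- dims[[i]]
      off <- off + Cs[i]
    }
    res
  })
}

# Row-concatenate feature matrices (C_i, N) -> (sum C_i, N)
ag_rbind <- function(xs) {
  xs <- lapply(xs, as_vt)
  rows <- vapply(xs, function(t) nrow(t$value), integer(1))
  val <- do.call(rbind, lapply(xs, function(t) t$value))
  ag_node(val, xs, function(g) {
    off <- 0L
    lapply(seq_along(xs), function(i) {
      r <- g[off + seq_len(rows[i]), , drop = FALSE]
      off <<- off + rows[i]
      r
    })
  })
}

# Fully connected layer: x (F, N), W (O, F), b length O -> (O, N)
ag_linear <- function(x, w, b) {
  x <- as_vt(x); w <- as_vt(w); b <- as_vt(b)
  xv <- x$value; wv <- w$value
  y <- wv %*% xv + b$value
  ag_node(y, list(x, w, b), function(g) {
    list(t(wv) %*% g, g %*% t(xv), rowSums(g))
  })
}

# ---- fused losses -----------------------------------------------------------

# Two-class voxel softmax + CE + soft Dice, fused for stability.
# logits: (d1,d2,d3,2,N); mask: (d1,d2,d3,N) in {0,1}.
# Returns a scalar vtensor whose value is l_ce + l_dice; the per-component
# values are attached as attributes "l_ce" and "l_dice".
ag_seg_loss <- function(logits, mask, eps = 1e-5, log_floor = 1e-12) {
  logits <- as_vt(logits)
  d <- dim(logits$value)
  V <- prod(d[1:3]); N <- d[5]
  z <- array(logits$value, c(V, 2, N))
  y1 <- array(as.numeric(mask), c(V, N))
  p1 <- 1 / (1 + exp(z[, 1, ] - z[, 2, ]))     # P(class = nodule)
  dim(p1) <- c(V, N)
  p0 <- 1 - p1
  ptrue <- ifelse(y1 > 0.5, p1, p0)
  ce_per <- colMeans(-log(pmax(ptrue, log_floor)))
  l_ce <- mean(ce_per)
  s_py <- colSums(p1 * y1)
  s_p <- colSums(p1)
  s_y <- colSums(y1)
  den <- s_p + s_y + eps
  dice_per <- 1 - (2 * s_py + eps) / den
  l_dice <- mean(dice_per)
  out <- ag_node(l_ce + l_dice, list(logits), function(g) {
    # CE: dz = (p - y) / (V * N); Dice: chain through p1 = softmax fg prob
    dz1_ce <- (p1 - y1) / (V * N)
    dp1_dice <- -(2 * y1 * rep(den, each = V) -
                    rep(2 * s_py + eps, each = V)) / rep(den^2, each = V)
    dz1_dice <- dp1_dice * p1 * p0 / N
    dz1 <- (dz1_ce + dz1_dice) * g
    dz <- array(0, c(V, 2, N))
    dz[, 2, ] <- dz1
    dz[, 1, ] <- -dz1
    dim(dz) <- d
    list(dz)
  })
  attr(out, "l_ce") <- l_ce
  attr(out, "l_dice") <- l_dice
  out
}

# Two-class softmax cross-entropy over a batch of samples.
# logits: (2, N); labels: vector of {0,1}, length N.
ag_cls_loss <- function(logits, labels, log_floor = 1e-12) {
  logits <- as_vt(logits)
  z <- logits$value
  N <- ncol(z)
  zmax <- pmax(z[1, ], z[2, ])
  ez <- exp(sweep(z, 2, zmax))
  p <- sweep(ez, 2, colSums(ez), "/")
  yi <- as.integer(labels) + 1L
  ptrue <- p[cbind(yi, seq_len(N))]
  l <- mean(-log(pmax(ptrue, log_floor)))
  ag_node(l, list(logits), function(g) {
    yh <- matrix(0, 2, N)
    yh[cbind(yi, seq_len(N))] <- 1
    list((p - yh) / N * g)
  })
}

ag_scalar_add <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}
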