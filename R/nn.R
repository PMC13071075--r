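# Layer constructors. A layer (or block) is a list with
#   $fwd    function mapping vtensor -> vtensor
#   $params named list of trainable vtensors
# Parameter initialization draws from the current RNG state, so building a
# model inside set.seed() is fully reproducible.

new_layer <- function(fwd, params = list()) list(fwd = fwd, params = params)

# Kaiming-style init for convolution weights: sd = sqrt(2 / fan_in)
conv_weight <- function(k, c_in_g, c_out) {
  fan_in <- c_in_g * k^3
  vt(array(stats::rnorm(k^3 * c_in_g * c_out, sd = sqrt(2 / fan_in)),
           c(k, k, k, c_in_g, c_out)), requires_grad = TRUE)
}

layer_conv3d <- function(c_in, c_out, k = 3L, stride = 1L, pad = NULL,
                         groups = 1L, dilation = 1L) {
  if (is.null(pad)) pad <- (dilation * (k - 1L)) %/% 2L   # "same" for odd k
  stopifnot(c_in %% groups == 0, c_out %% groups == 0)
  w <- conv_weight(k, c_in %/% groups, c_out)
  b <- vt(numeric(c_out), requires_grad = TRUE)
  new_layer(
    fwd = function(x) ag_conv3d(x, w, b, stride, pad, dilation, groups),
    params = list(w = w, b = b)
  )
}

# Number of normalization groups: largest divisor of C not exceeding 8
gn_groups <- function(C) {
  g <- min(8L, C)
  while (C %% g != 0L) g <- g - 1L
  g
}

layer_group_norm <- function(C, groups = NULL) {
  if (is.null(groups)) groups <- gn_groups(C)
  gamma <- vt(rep(1, C), requires_grad = TRUE)
  beta <- vt(numeric(C), requires_grad = TRUE)
  new_layer(
    fwd = function(x) ag_group_norm(x, gamma, beta, groups),
    params = list(gamma = gamma, beta = beta)
  )
}

layer_linear <- function(f_in, f_out) {
  w <- vt(matrix(stats::rnorm(f_out * f_in, sd = sqrt(2 / f_in)), f_out, f_in),
          requires_grad = TRUE)
  b <- vt(numeric(f_out), requires_grad = TRUE)
  new_layer(
    fwd = function(x) ag_linear(x, w, b),
    params = list(w = w, b = b)
  )
}

# conv -> group norm -> ReLU, the standard unit used throughout
layer_cnr <- function(c_in, c_out, k = 3L, stride = 1L, groups = 1L,
                      dilation = 1L) {
  cv <- layer_conv3d(c_in, c_out, k, stride, groups = groups,
                     dilation = dilation)
  gn <- layer_group_norm(c_out)
  new_layer(
    fwd = function(x) ag_relu(gn$fwd(cv$fwd(x))),
    params = c(conv = cv$params, gn = gn$params)
  )
}

identity_layer <- function() new_layer(fwd = function(x) x)

# Flatten the parameters of a named list of layers into one named list
collect_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    ps <- layers[[nm]]$params
    if (length(ps)) {
      names(ps) <- paste(nm, names(ps), sep = ".")
      out <- c(out, ps)
    }
  }
  out
}

n_params <- function(params) sum(vapply(params, function(p) length(p$value),
                                        numeric(1)))

# ---- SGD with momentum and weight decay ------------------------------------

#' Create an SGD optimizer state
#' @param params Named list of trainable `vtensor`s.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty coefficient (decoupled into the gradient,
#'   the classical formulation).
#' @keywords internal
sgd_new <- function(params, lr = 0.01, momentum = 0.9, weight_decay = 1e-4) {
  list(params = params, lr = lr, momentum = momentum,
       weight_decay = weight_decay,
       velocity = lapply(params, function(p) p$value * 0))
}

sgd_step <- function(opt) {
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + opt$weight_decay * p$value
    opt$velocity[[i]] <- opt$momentum * opt$velocity[[i]] + g
    p$value <- p$value - opt$lr * opt$velocity[[i]]
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
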