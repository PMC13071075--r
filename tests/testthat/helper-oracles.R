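# Independent oracles and shared fixtures for the test suite.

# Naive single-branch grouped 3D convolution, written as plain loops —
# independent of the vol2col/GEMM path it is used to check.
naive_conv3d <- function(x, w, b, stride = 1L, pad = 0L, dilation = 1L,
                         groups = 1L) {
  d <- dim(x)                      # (d1, d2, d3, C)
  k <- dim(w)[1]                   # (k, k, k, C/groups, c_out)
  cg <- dim(w)[4]; c_out <- dim(w)[5]
  og <- c_out / groups
  osz <- (d[1:3] + 2 * pad - dilation * (k - 1) - 1) %/% stride + 1
  y <- array(0, c(osz, c_out))
  for (co in seq_len(c_out)) {
    g <- (co - 1) %/% og
    cin <- g * cg + seq_len(cg)
    for (j3 in seq_len(osz[3])) for (j2 in seq_len(osz[2]))
      for (j1 in seq_len(osz[1])) {
        acc <- b[co]
        for (k3 in seq_len(k)) for (k2 in seq_len(k))
          for (k1 in seq_len(k)) {
            i1 <- (j1 - 1) * stride - pad + (k1 - 1) * dilation + 1
            i2 <- (j2 - 1) * stride - pad + (k2 - 1) * dilation + 1
            i3 <- (j3 - 1) * stride - pad + (k3 - 1) * dilation + 1
            if (i1 >= 1 && i1 <= d[1] && i2 >= 1 && i2 <= d[2] &&
                i3 >= 1 && i3 <= d[3])
              acc <- acc + sum(x[i1, i2, i3, cin] * w[k1, k2, k3, , co])
          }
        y[j1, j2, j3, co] <- acc
      }
  }
  y
}

# Central finite-difference gradient of scalar f at x
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# Rasterized ball mask on a cubic grid (independent geometry oracle)
ball_mask <- function(shape, radius_mm, spacing = c(1, 1, 1)) {
  ctr <- ceiling(shape / 2)
  g <- as.matrix(expand.grid(seq_len(shape[1]), seq_len(shape[2]),
                             seq_len(shape[3])))
  mm <- sweep(g, 2, ctr) %*% diag(spacing)
  m <- array(0, shape)
  m[g[rowSums(mm^2) <= radius_mm^2, , drop = FALSE]] <- 1
  m
}

# Desk-scale network configuration used across training tests
small_net <- function(seed = 1L, stage_channels = c(8L, 16L, 32L, 64L), ...) {
  network_config(stage_channels = stage_channels, patch_size = 32L,
                 seed = seed, ...)
}

# One shared phantom cohort per test run (generated once, reused)
.fixture_env <- new.env()
shared_cohort <- function(n = 8L, seed = 42L) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), key)
    generate_cohort(n, 0.5, seed = seed, out_dir = dir)
    .fixture_env[[key]] <- file.path(dir, "manifest.csv")
  }
  read_manifest(.fixture_env[[key]])
}

# Access to internal autograd helpers used by oracle tests
ns <- asNamespace("nodulemt")
vt_ <- ns$vt
ag_backward_ <- ns$ag_backward
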