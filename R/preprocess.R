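# Preprocessing chain: isotropic resampling, HU clipping and normalization,
# lesion-centered patch extraction, and train-time augmentation.

#' Resample a volume/mask pair to isotropic spacing
#'
#' Output shape per axis is \code{round(shape * spacing / target_mm)}; the
#' image is interpolated trilinearly, the mask by nearest neighbour (so it
#' stays strictly binary). Uses the half-pixel-center convention.
#'
#' @param vol A \code{\link{ct_volume}} in HU.
#' @param mask Binary array aligned with \code{vol} (optional).
#' @param target_mm Target isotropic spacing (default 1 mm).
#' @return List with resampled \code{vol} and \code{mask} (NULL if absent).
#' @export
resample_isotropic <- function(vol, mask = NULL, target_mm = 1) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity != "HU")
    stop("resample_isotropic: expected a volume in HU")
  if (target_mm <= 0) stop("resample_isotropic: non-positive target spacing")
  d <- dim(vol$data)
  od <- as.integer(round(d * vol$spacing / target_mm))
  x5 <- as.numeric(vol$data)
  y <- cpp_trilinear_resize(x5, as.integer(c(d, 1L, 1L)),
                            as.integer(c(od, 1L, 1L)))
  out_vol <- ct_volume(array(y, od), spacing = rep(target_mm, 3),
                       intensity = "HU")
  out_mask <- NULL
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), d))
    m <- cpp_nearest_resize(as.numeric(mask), as.integer(c(d, 1L, 1L)),
                            as.integer(c(od, 1L, 1L)))
    out_mask <- array(m, od)
  }
  list(vol = out_vol, mask = out_mask)
}

#' Clip and normalize Hounsfield units
#'
#' Clips intensities to [-1000, 400] HU (air to soft tissue / calcification,
#' the lung-relevant range) and maps the result linearly to [0, 1]:
#' \code{(clip(x, -1000, 400) + 1000) / 1400}.
#'
#' @param vol A \code{\link{ct_volume}} in HU.
#' @param hu_min,hu_max Clipping bounds (defaults -1000, 400).
#' @return The normalized \code{ct_volume} (\code{intensity = "normalized"}).
#' @export
clip_normalize_hu <- function(vol, hu_min = -1000, hu_max = 400) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity == "normalized")
    stop("clip_normalize_hu: volume is already normalized")
  x <- pmin(pmax(vol$data, hu_min), hu_max)
  ct_volume((x - hu_min) / (hu_max - hu_min), spacing = vol$spacing,
            intensity = "normalized")
}

#' Labeled network-ready patch
#'
#' @param image Normalized intensity array, cube of edge \code{size}.
#' @param mask Binary array of the same shape.
#' @param label 0 (benign) or 1 (malignant).
#' @param case_id,center Provenance: source case and 1-based center voxel.
#' @return A validated \code{labeled_patch}.
#' @export
labeled_patch <- function(image, mask, label, case_id = NA_character_,
                          center = NULL) {
  stopifnot(identical(dim(image), dim(mask)),
            length(unique(dim(image))) == 1)
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("labeled_patch: image intensities must lie in [0, 1]")
  if (!all(as.numeric(mask) %in% c(0, 1)))
    stop("labeled_patch: mask must be binary")
  structure(list(image = image, mask = mask, label = as.integer(label),
                 case_id = case_id, center = center),
            class = "labeled_patch")
}

#' Extract a lesion-centered cubic patch
#'
#' Returns a patch of edge \code{size} whose (0-based) index \code{size/2}
#' on each axis is the requested center voxel — i.e. R index
#' \code{size/2 + 1}. Regions falling outside the volume are padded with 0
#' (air after normalization) for the image and 0 for the mask.
#'
#' @param vol A normalized \code{\link{ct_volume}}.
#' @param mask Binary array aligned with \code{vol}.
#' @param center Integer vector (3), 1-based center voxel.
#' @param size Patch edge (default 64, must be even).
#' @param label Malignancy label carried into the patch.
#' @param case_id Provenance id.
#' @return A \code{\link{labeled_patch}}.
#' @export
extract_patch <- function(vol, mask, center, size = 64L, label = 0L,
                          case_id = NA_character_) {
  stopifnot(inherits(vol, "ct_volume"), size %% 2L == 0L)
  if (vol$intensity != "normalized")
    stop("extract_patch: volume must be normalized first")
  d <- dim(vol$data)
  center <- as.integer(center)
  if (any(center < 1L) || any(center > d))
    stop("extract_patch: center voxel ", paste(center, collapse = ","),
         " outside volume ", paste(d, collapse = "x"))
  half <- size %/% 2L
  img <- array(0, rep(size, 3))
  msk <- array(0, rep(size, 3))
  lo <- center - half            # source start (may be < 1)
  src <- lapply(1:3, function(a) {
    s <- max(1L, lo[a]); e <- min(d[a], lo[a] + size - 1L)
    list(src = s:e, dst = (s - lo[a] + 1L):(e - lo[a] + 1L))
  })
  img[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst] <-
    vol$data[src[[1]]$src, src[[2]]$src, src[[3]]$src]
  msk[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst] <-
    mask[src[[1]]$src, src[[2]]$src, src[[3]]$src]
  labeled_patch(img, msk, label, case_id, center)
}

#' Augmentation configuration
#'
#' @param p_rotate,p_elastic,p_flip,p_noise Per-transform application
#'   probabilities.
#' @param noise_sd Gaussian noise sd on the normalized intensity scale.
#' @param elastic_grid Control points per axis of the coarse displacement
#'   field.
#' @param elastic_alpha Displacement amplitude sd in voxels.
#' @return Augmentation config list.
#' @export
augment_config <- function(p_rotate = 0.5, p_elastic = 0.5, p_flip = 0.5,
                           p_noise = 0.5, noise_sd = 0.02,
                           elastic_grid = 4L, elastic_alpha = 1.5) {
  list(p_rotate = p_rotate, p_elastic = p_elastic, p_flip = p_flip,
       p_noise = p_noise, noise_sd = noise_sd,
       elastic_grid = as.integer(elastic_grid),
       elastic_alpha = elastic_alpha)
}

# Rotate a cube by 90 degrees in the plane of axes (a, b)
rot90_cube <- function(a, axes) {
  perm <- 1:3
  perm[axes] <- rev(axes)
  out <- aperm(a, perm)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axes[1]]] <- rev(seq_len(dim(out)[axes[1]]))
  do.call(`[`, c(list(out), idx, list(drop = FALSE)))
}

# Trilinear sampling of cube `a` at continuous 1-based coords (n x 3);
# out-of-range coordinates clamp to the edge.
sample_trilinear <- function(a, coords) {
  d <- dim(a)
  cl <- sapply(1:3, function(k) pmin(pmax(coords[, k], 1), d[k]))
  lo <- floor(cl); hi <- pmin(lo + 1, rep(d, each = nrow(cl)))
  w <- cl - lo
  g <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- g(lo[,1], lo[,2], lo[,3]); v100 <- g(hi[,1], lo[,2], lo[,3])
  v010 <- g(lo[,1], hi[,2], lo[,3]); v110 <- g(hi[,1], hi[,2], lo[,3])
  v001 <- g(lo[,1], lo[,2], hi[,3]); v101 <- g(hi[,1], lo[,2], hi[,3])
  v011 <- g(lo[,1], hi[,2], hi[,3]); v111 <- g(hi[,1], hi[,2], hi[,3])
  (((v000 * (1 - w[,1]) + v100 * w[,1]) * (1 - w[,2]) +
    (v010 * (1 - w[,1]) + v110 * w[,1]) * w[,2]) * (1 - w[,3])) +
  (((v001 * (1 - w[,1]) + v101 * w[,1]) * (1 - w[,2]) +
    (v011 * (1 - w[,1]) + v111 * w[,1]) * w[,2]) * w[,3])
}

# Nearest-neighbour sampling (keeps masks binary)
sample_nearest <- function(a, coords) {
  d <- dim(a)
  idx <- sapply(1:3, function(k) pmin(pmax(round(coords[, k]), 1), d[k]))
  a[idx]
}

# Smooth random displacement field: coarse grid upsampled trilinearly
elastic_field <- function(size, grid, alpha) {
  field <- array(0, c(size, size, size, 3))
  for (ax in 1:3) {
    coarse <- array(stats::rnorm(grid^3, 0, alpha), rep(grid, 3))
    up <- cpp_trilinear_resize(as.numeric(coarse),
                               as.integer(c(grid, grid, grid, 1L, 1L)),
                               as.integer(c(size, size, size, 1L, 1L)))
    field[, , , ax] <- array(up, rep(size, 3))
  }
  field
}

#' Augment a labeled patch
#'
#' Applies, each with its configured probability and in this order:
#' axis-aligned 90-degree rotation (random plane, random quarter turns),
#' elastic deformation (one shared displacement field; image trilinear, mask
#' nearest), axis flips (random subset of axes), and additive Gaussian noise
#' on the image only, re-clipped to [0, 1]. Image and mask receive identical
#' geometric transforms; the label is unchanged. Fully determined by
#' \code{seed}.
#'
#' @param patch A \code{\link{labeled_patch}}.
#' @param params An \code{\link{augment_config}}.
#' @param seed Integer seed for this call.
#' @return The augmented \code{\link{labeled_patch}}.
#' @export
augment_patch <- function(patch, params = augment_config(), seed = 1L) {
  stopifnot(inherits(patch, "labeled_patch"))
  img <- patch$image; msk <- patch$mask
  size <- dim(img)[1]
  with_seed(seed, {
    if (stats::runif(1) < params$p_rotate) {
      axes <- sort(sample(1:3, 2))
      turns <- sample(1:3, 1)
      for (t in seq_len(turns)) {
        img <- rot90_cube(img, axes)
        msk <- rot90_cube(msk, axes)
      }
    }
    if (stats::runif(1) < params$p_elastic) {
      disp <- elastic_field(size, params$elastic_grid, params$elastic_alpha)
      base <- as.matrix(expand.grid(i = seq_len(size), j = seq_len(size),
                                    k = seq_len(size)))
      coords <- base + cbind(as.numeric(disp[, , , 1]),
                             as.numeric(disp[, , , 2]),
                             as.numeric(disp[, , , 3]))
      img <- array(sample_trilinear(img, coords), dim(img))
      msk <- array(sample_nearest(msk, coords), dim(msk))
    }
    if (stats::runif(1) < params$p_flip) {
      for (ax in sample(1:3, sample(1:3, 1))) {
        idx <- rep(list(quote(expr = )), 3)
        idx[[ax]] <- rev(seq_len(size))
        img <- do.call(`[`, c(list(img), idx, list(drop = FALSE)))
        msk <- do.call(`[`, c(list(msk), idx, list(drop = FALSE)))
      }
    }
    if (stats::runif(1) < params$p_noise) {
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sd),
                         dim(img))
      img <- pmin(pmax(img, 0), 1)
    }
  })
  labeled_patch(img, msk, patch$label, patch$case_id, patch$center)
}

#' Load and preprocess one manifest row into a network-ready patch
#'
#' Reads the NIfTI pair, resamples to 1 mm isotropic spacing if needed,
#' clips/normalizes HU, and extracts the lesion-centered patch.
#'
#' @param manifest A manifest data.frame (see \code{\link{read_manifest}}).
#' @param row Row index.
#' @param patch_size Patch edge in voxels.
#' @return A \code{\link{labeled_patch}}.
#' @export
load_patch <- function(manifest, row, patch_size = 64L) {
  r <- manifest[row, ]
  vol <- read_volume(manifest_path(manifest, r$image_path))
  msk <- read_volume(manifest_path(manifest, r$mask_path))$data
  msk <- as.numeric(msk > 0.5); dim(msk) <- dim(vol$data)
  center <- c(r$center_z, r$center_y, r$center_x) + 1L
  if (any(abs(vol$spacing - 1) > 1e-6)) {
    rs <- resample_isotropic(vol, msk, target_mm = 1)
    center <- pmax(1L, pmin(dim(rs$vol$data),
                            as.integer(round(center * vol$spacing))))
    vol <- rs$vol; msk <- rs$mask
  }
  vol <- clip_normalize_hu(vol)
  extract_patch(vol, msk, center, size = patch_size, label = r$label,
                case_id = r$case_id)
}
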