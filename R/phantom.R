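# Synthetic nodule-phantom generator. Produces CT-like volumes (Hounsfield
# units) containing one star-shaped nodule with a voxel-wise ground-truth
# mask and a benign/malignant label, plus vessel-like tubular clutter and
# Gaussian noise, so the full pipeline can train and evaluate with no
# external data.
#
# Volume arrays are indexed (z, y, x); manifests store 0-based voxel indices
# as center_z, center_y, center_x for the three array dimensions in order.

# Run expr under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Deterministic quasi-uniform directions on the sphere (Fibonacci lattice),
# used to normalize the angular perturbation to zero mean and unit max-abs.
fibonacci_sphere <- function(n = 400) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Phantom specification
#'
#' Parameters of one synthetic nodule phantom. The nodule boundary is the
#' star-shaped surface \eqn{r(\theta,\phi) = r_0 (1 + a\, s(\theta,\phi))}
#' where \eqn{s} is a smooth zero-mean angular perturbation with
#' \code{spike_count} radial lobes (sum of von-Mises-like bumps at seeded
#' random orientations, normalized to max |s| = 1), so \code{a < 1}
#' guarantees a positive radius everywhere.
#'
#' @param volume_shape Integer vector (3), voxels per axis.
#' @param spacing_mm Numeric vector (3), voxel size in mm.
#' @param nodule_radius_mm Base radius r0 in mm, within [1.5, 15]
#'   (3-30 mm diameter).
#' @param spiculation_amplitude Dimensionless a in [0, 1): radial
#'   perturbation scale.
#' @param spike_count Integer >= 0, number of radial lobes.
#' @param nodule_hu Mean nodule intensity (HU).
#' @param background_hu Mean lung-parenchyma intensity (HU).
#' @param noise_sigma_hu Additive Gaussian noise scale (HU).
#' @param vessel_count Integer >= 0, tubular clutter structures.
#' @param label 0 = benign, 1 = malignant.
#' @param seed Integer RNG seed; identical specs give bit-identical output.
#' @return A validated \code{phantom_spec} list.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 64L),
                         spacing_mm = c(1, 1, 1),
                         nodule_radius_mm = 5,
                         spiculation_amplitude = 0,
                         spike_count = 0L,
                         nodule_hu = -50,
                         background_hu = -800,
                         noise_sigma_hu = 40,
                         vessel_count = 0L,
                         label = 0L,
                         seed = 1L) {
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 8),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            nodule_radius_mm >= 1.5, nodule_radius_mm <= 15,
            spiculation_amplitude >= 0, spiculation_amplitude < 1,
            spike_count >= 0, vessel_count >= 0,
            noise_sigma_hu >= 0, label %in% c(0L, 1L))
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 nodule_radius_mm = nodule_radius_mm,
                 spiculation_amplitude = spiculation_amplitude,
                 spike_count = as.integer(spike_count),
                 nodule_hu = nodule_hu, background_hu = background_hu,
                 noise_sigma_hu = noise_sigma_hu,
                 vessel_count = as.integer(vessel_count),
                 label = as.integer(label), seed = as.integer(seed)),
            class = "phantom_spec")
}

# 1-based center voxel of a volume
phantom_center <- function(spec) ceiling(spec$volume_shape / 2)

# Angular perturbation evaluator: returns function(u) for unit rows u,
# already zero-mean and max-abs normalized over a probe lattice.
make_perturbation <- function(spec) {
  if (spec$spike_count == 0L || spec$spiculation_amplitude == 0)
    return(function(u) numeric(nrow(u)))
  dirs <- with_seed(spec$seed, {
    v <- matrix(stats::rnorm(3 * spec$spike_count), ncol = 3)
    v / sqrt(rowSums(v^2))
  })
  kappa <- 3 + spec$spike_count      # sharper lobes as their number grows
  raw <- function(u) {
    s <- numeric(nrow(u))
    for (j in seq_len(nrow(dirs)))
      s <- s + exp(kappa * (u %*% dirs[j, ] - 1))
    as.numeric(s)
  }
  probe <- fibonacci_sphere(400)
  m <- mean(raw(probe))
  M <- max(abs(raw(probe) - m))
  if (M == 0) return(function(u) numeric(nrow(u)))
  function(u) (raw(u) - m) / M
}

#' Rasterize the ground-truth nodule mask of a phantom
#'
#' Voxelizes the star-shaped region \eqn{r \le r_0 (1 + a\, s(u))} around
#' the volume center; a voxel belongs to the nodule when its physical center
#' lies inside the surface.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return Binary array of \code{spec$volume_shape}.
#' @export
make_nodule_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ctr <- phantom_center(spec)
  rmax <- spec$nodule_radius_mm * (1 + spec$spiculation_amplitude)
  half_extent <- (spec$volume_shape / 2 - 1) * spec$spacing_mm
  if (any(rmax + max(spec$spacing_mm) > half_extent))
    stop("phantom geometry error: nodule (max radius ", round(rmax, 2),
         " mm) would cross the volume boundary")
  s_fun <- make_perturbation(spec)
  nb <- ceiling(rmax / spec$spacing_mm) + 1L
  idx <- lapply(1:3, function(a) (ctr[a] - nb[a]):(ctr[a] + nb[a]))
  grid <- as.matrix(expand.grid(z = idx[[1]], y = idx[[2]], x = idx[[3]]))
  mm <- sweep(grid, 2, ctr) %*% diag(spec$spacing_mm)
  rad <- sqrt(rowSums(mm^2))
  inside <- rad <= 1e-9
  nz <- !inside
  if (any(nz)) {
    u <- mm[nz, , drop = FALSE] / rad[nz]
    rb <- spec$nodule_radius_mm *
      (1 + spec$spiculation_amplitude * s_fun(u))
    inside[nz] <- rad[nz] <= rb
  }
  mask <- array(0, spec$volume_shape)
  mask[grid[inside, , drop = FALSE]] <- 1
  mask
}

# 3^3 box blur via the grouped-conv kernel (used for boundary smoothing)
box_blur3 <- function(a) {
  d <- dim(a)
  w <- array(1 / 27, c(3, 3, 3, 1, 1))
  y <- cpp_conv3d_forward(as.numeric(a), as.integer(c(d, 1L, 1L)),
                          w, 0, 3L, 1L, 1L, 1L, 1L, 1L)
  array(y, d)
}

#' Render a phantom CT volume from its mask
#'
#' Background parenchyma at \code{background_hu}, nodule voxels at
#' \code{nodule_hu}, optional straight-cylinder vessels of near-nodule
#' intensity grazing the nodule surface (not added to the mask), additive
#' Gaussian noise, and partial-volume boundary smoothing. Smoothing emulates
#' the scanner point-spread function and is applied only when
#' \code{noise_sigma_hu > 0}; the noiseless setting renders a strict
#' two-valued volume for testing.
#'
#' @param mask Binary array from \code{\link{make_nodule_mask}}.
#' @param spec The matching \code{\link{phantom_spec}}.
#' @return A \code{\link{ct_volume}} in Hounsfield units.
#' @export
render_phantom <- function(mask, spec) {
  stopifnot(inherits(spec, "phantom_spec"),
            identical(as.integer(dim(mask)), spec$volume_shape))
  contrast <- spec$nodule_hu - spec$background_hu
  img <- spec$background_hu + contrast * mask
  with_seed(spec$seed + 1L, {
    if (spec$vessel_count > 0) {
      ctr <- phantom_center(spec)
      d <- dim(img)
      grid <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                                    x = seq_len(d[3])))
      mm <- sweep(grid, 2, ctr) %*% diag(spec$spacing_mm)
      rsurf <- spec$nodule_radius_mm * (1 + spec$spiculation_amplitude)
      for (v in seq_len(spec$vessel_count)) {
        udir <- stats::rnorm(3); udir <- udir / sqrt(sum(udir^2))
        vdir <- stats::rnorm(3); vdir <- vdir / sqrt(sum(vdir^2))
        q <- udir * (rsurf + stats::runif(1, 0.5, 2))  # grazes the surface
        rel <- sweep(mm, 2, q)
        proj <- as.numeric(rel %*% vdir)
        dist2 <- rowSums(rel^2) - proj^2
        rv <- stats::runif(1, 1, 2) * min(spec$spacing_mm)
        hit <- dist2 <= rv^2 & mask[grid] == 0
        img[grid[hit, , drop = FALSE]] <-
          spec$nodule_hu + stats::runif(1, -30, 10)
      }
    }
    if (spec$noise_sigma_hu > 0) {
      # partial-volume halo just outside the boundary: replace the sharp
      # mask contribution by max(blur(mask), mask), so the interior keeps
      # nodule_hu exactly (in-mask mean stays unbiased) while boundary
      # voxels decay smoothly; vessel intensities are preserved additively
      w <- pmax(box_blur3(mask + 0), mask)
      img <- img + contrast * (w - mask)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma_hu),
                         dim(img))
    }
  })
  ct_volume(img, spacing = spec$spacing_mm, intensity = "HU")
}

# Class-conditional parameter distributions: malignant nodules are larger,
# more spiculated and higher-contrast than benign ones.
draw_phantom_params <- function(label) {
  if (label == 1L) {
    list(nodule_radius_mm = stats::runif(1, 5, 15),
         spiculation_amplitude = stats::runif(1, 0.15, 0.4),
         spike_count = sample(6:14, 1),
         nodule_hu = stats::runif(1, 0, 100))
  } else {
    list(nodule_radius_mm = stats::runif(1, 1.5, 6),
         spiculation_amplitude = stats::runif(1, 0, 0.1),
         spike_count = sample(0:4, 1),
         nodule_hu = stats::runif(1, -100, 0))
  }
}

#' Generate a phantom cohort on disk
#'
#' Writes \code{n} NIfTI image/mask pairs (shared affine and spacing) plus a
#' CSV manifest with header
#' \code{case_id,image_path,mask_path,label,center_z,center_y,center_x}
#' (0-based voxel indices, paths relative to the manifest). Class-conditional
#' parameters: benign r0 in [1.5, 6] mm with spiculation in [0, 0.1];
#' malignant r0 in [5, 15] mm, spiculation in [0.15, 0.4], 6-14 spikes and
#' higher intensity; background -800 HU, noise 40 HU, 0-3 vessels. The whole
#' cohort is a pure function of (n, malignant_fraction, seed).
#'
#' @param n Number of cases (>= 2).
#' @param malignant_fraction Fraction labeled malignant; the malignant count
#'   is \code{round(n * malignant_fraction)}.
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if missing).
#' @param volume_shape,spacing_mm Geometry passed to every phantom.
#' @param noise_sigma_hu,vessel_max Noise scale and maximum vessels per case.
#' @return The manifest as a data.frame (invisibly written to
#'   \code{out_dir/manifest.csv}); attribute \code{"dir"} holds
#'   \code{out_dir}.
#' @export
generate_cohort <- function(n, malignant_fraction = 0.5, seed = 1L,
                            out_dir = tempfile("cohort"),
                            volume_shape = c(64L, 64L, 64L),
                            spacing_mm = c(1, 1, 1),
                            noise_sigma_hu = 40, vessel_max = 3L) {
  stopifnot(n >= 2, malignant_fraction >= 0, malignant_fraction <= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("generate_cohort: cannot create output directory ", out_dir)
  n_mal <- round(n * malignant_fraction)
  rows <- with_seed(seed, {
    labels <- sample(c(rep(1L, n_mal), rep(0L, n - n_mal)))
    case_seeds <- sample.int(.Machine$integer.max - 2L, n)
    lapply(seq_len(n), function(i) {
      pars <- draw_phantom_params(labels[i])
      c(list(label = labels[i], seed = case_seeds[i],
             vessel_count = sample(0:vessel_max, 1)), pars)
    })
  })
  man <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    spec <- phantom_spec(volume_shape = volume_shape,
                         spacing_mm = spacing_mm,
                         nodule_radius_mm = r$nodule_radius_mm,
                         spiculation_amplitude = r$spiculation_amplitude,
                         spike_count = r$spike_count,
                         nodule_hu = r$nodule_hu,
                         noise_sigma_hu = noise_sigma_hu,
                         vessel_count = r$vessel_count,
                         label = r$label, seed = r$seed)
    mask <- make_nodule_mask(spec)
    vol <- render_phantom(mask, spec)
    case_id <- sprintf("case_%04d", i)
    ipath <- paste0(case_id, "_image.nii.gz")
    mpath <- paste0(case_id, "_mask.nii.gz")
    write_volume(vol, file.path(out_dir, ipath))
    write_volume(ct_volume(mask, spacing = spec$spacing_mm,
                           intensity = "HU"),
                 file.path(out_dir, mpath))
    ctr0 <- phantom_center(spec) - 1L
    man[[i]] <- data.frame(case_id = case_id, image_path = ipath,
                           mask_path = mpath, label = r$label,
                           center_z = ctr0[1], center_y = ctr0[2],
                           center_x = ctr0[3], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, man)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path Path to a manifest CSV; relative image/mask paths are
#'   resolved against its directory.
#' @return Manifest data.frame with attribute \code{"dir"}.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "image_path", "mask_path", "label",
            "center_z", "center_y", "center_x")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  attr(man, "dir") <- dirname(normalizePath(path))
  man
}

# Resolve a manifest-relative path
manifest_path <- function(manifest, p) {
  base <- attr(manifest, "dir")
  ifelse(file.exists(p), p, file.path(base, p))
}
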