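# CTVolume container and NIfTI I/O (via RNifti). Arrays are indexed
# (z, y, x); spacing is the per-axis voxel size in mm.

#' CT volume container
#'
#' A dense 3-D scalar field with physical spacing, carrying either raw
#' Hounsfield units or normalized [0, 1] intensities.
#'
#' @param data Numeric 3-D array (z, y, x).
#' @param spacing Positive numeric vector (3), voxel size in mm.
#' @param intensity Either "HU" or "normalized".
#' @return A \code{ct_volume} object.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), intensity = c("HU", "normalized")) {
  intensity <- match.arg(intensity)
  stopifnot(is.numeric(data), length(dim(data)) == 3,
            length(spacing) == 3)
  if (any(spacing <= 0)) stop("ct_volume: spacing must be strictly positive")
  if (intensity == "normalized" &&
      (min(data) < -1e-9 || max(data) > 1 + 1e-9))
    stop("ct_volume: normalized intensities must lie in [0, 1]")
  structure(list(data = data, spacing = as.numeric(spacing),
                 intensity = intensity),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume %s, spacing %s mm, %s, range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              x$intensity, min(x$data), max(x$data)))
  invisible(x)
}

#' Write a CT volume (or mask) as gzipped NIfTI
#'
#' @param vol A \code{\link{ct_volume}}.
#' @param path Output path (.nii or .nii.gz).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param intensity Intensity space to tag the result with.
#' @return A \code{\link{ct_volume}} with spacing from the file header.
#' @export
read_volume <- function(path, intensity = "HU") {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim(img)),
            spacing = RNifti::pixdim(img)[1:3], intensity = intensity)
}
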