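#' Hounsfield-calibrated 3D volume
#'
#' Container for a 3D grid of Hounsfield units (HU) with isotropic voxel
#' spacing, the image under analysis throughout the package. Values must lie
#' in the representable CT range \[-1024, 3071\] and each grid axis must have
#' at least 8 voxels.
#'
#' @param data 3D numeric array of Hounsfield units.
#' @param spacing_mm Positive scalar isotropic voxel spacing in millimetres.
#' @param origin_mm Numeric 3-vector, physical position of the first voxel.
#' @param meta Free-form list of provenance tags.
#' @return An object of class `hu_volume`: a list with elements `data`,
#'   `spacing_mm`, `origin_mm`, `meta`.
#' @examples
#' v <- hu_volume(array(-650, c(8, 8, 8)), spacing_mm = 0.2)
#' dim(v$data)
#' @export
hu_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_input("`data` must be a 3D array")
  }
  if (any(dim(data) < 8L)) {
    abort_input("grid dimensions must be >= 8 along each axis")
  }
  if (!is_scalar(spacing_mm) || spacing_mm <= 0) {
    abort_input("`spacing_mm` must be a positive scalar")
  }
  rng <- range(data)
  if (rng[1] < -1024 || rng[2] > 3071) {
    abort_input("HU values must lie within [-1024, 3071]")
  }
  if (length(origin_mm) != 3L || !is.numeric(origin_mm)) {
    abort_input("`origin_mm` must be a numeric 3-vector")
  }
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm), meta = meta),
    class = "hu_volume"
  )
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hu_volume> %d x %d x %d voxels @ %.3f mm (HU %.0f .. %.0f)\n",
              d[1], d[2], d[3], x$spacing_mm, min(x$data), max(x$data)))
  invisible(x)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Convolves along each axis with a normalised Gaussian kernel truncated at
#' four standard deviations; the kernel is renormalised at the borders
#' (equivalent to normalised convolution), so flat regions are preserved.
#'
#' @param a 3D numeric array.
#' @param sigma_vox Gaussian standard deviation in voxels; 0 returns `a`.
#' @return Smoothed array of the same dimensions.
#' @keywords internal
gaussian_smooth3 <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  smooth_first_axis <- function(x, sigma) {
    n <- dim(x)[1]
    half <- max(1L, ceiling(4 * sigma))
    offs <- (-half):half
    w <- dnorm(offs, sd = sigma)
    K <- matrix(0, n, n)
    for (t in seq_along(offs)) {
      src <- seq_len(n) + offs[t]
      ok <- src >= 1L & src <= n
      K[cbind(which(ok), src[ok])] <- K[cbind(which(ok), src[ok])] + w[t]
    }
    K <- K / rowSums(K)
    array(K %*% matrix(x, n, prod(dim(x)[-1])), dim(x))
  }
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(smooth_first_axis(aperm(a, perm), sigma_vox), order(perm))
  }
  a
}
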