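# File-format plumbing: NIfTI-1 volumes and masks, JSON seed lists and
# segmentation reports, YAML run configuration.

#' Write / read an HU volume as NIfTI-1
#'
#' The isotropic spacing is stored in the NIfTI pixdim; masks and
#' compartment-label grids are written as 8-bit companion images on the same
#' grid.
#'
#' @param volume An [hu_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_hu_nifti` returns `path` invisibly; `read_hu_nifti`
#'   returns an [hu_volume()].
#' @export
write_hu_nifti <- function(volume, path) {
  arr <- volume$data
  attr(arr, "pixdim") <- rep(volume$spacing_mm, 3)
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_hu_nifti
#' @export
read_hu_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(im)[1:3]
  if (max(pd) - min(pd) > 1e-6 * max(pd)) {
    abort_input("NIfTI volume is not isotropic: pixdim ",
                paste(signif(pd, 6), collapse = " x "))
  }
  hu_volume(array(as.numeric(im), dim(im)), spacing_mm = pd[1],
            meta = list(source = path))
}

#' Write a label or mask grid as 8-bit NIfTI-1
#'
#' @param labels Integer or logical 3D array (values 0-255).
#' @param spacing_mm Isotropic spacing in mm.
#' @param path Output path.
#' @return `path`, invisibly; `read_label_nifti` returns an integer array
#'   with attribute `spacing_mm`.
#' @export
write_label_nifti <- function(labels, spacing_mm, path) {
  arr <- array(as.integer(labels), dim(labels))
  attr(arr, "pixdim") <- rep(spacing_mm, 3)
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' @rdname write_label_nifti
#' @export
read_label_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  out <- array(as.integer(im), dim(im))
  attr(out, "spacing_mm") <- RNifti::pixdim(im)[1]
  out
}

#' Write / read a seed set as JSON
#'
#' On disk, seeds are stored 0-based in (k, j, i) order; in memory the
#' package uses 1-based (i, j, k) R array indices. The conversion is
#' performed here.
#'
#' @param seeds A [seed_set()].
#' @param path File path.
#' @return `write_seed_json` returns `path` invisibly; `read_seed_json`
#'   returns a [seed_set()].
#' @export
write_seed_json <- function(seeds, path) {
  s <- seeds$seeds
  kji0 <- unname(cbind(s[, 3], s[, 2], s[, 1]) - 1L)
  jsonlite::write_json(
    list(label = seeds$label, provenance = seeds$provenance,
         index_convention = "0-based (k, j, i)",
         seeds = kji0),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_seed_json
#' @param min_seeds,max_seeds Protocol bounds passed to [seed_set()].
#' @export
read_seed_json <- function(path, min_seeds = 1L, max_seeds = 1000L) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kji0 <- as.matrix(obj$seeds)
  ijk1 <- cbind(kji0[, 3], kji0[, 2], kji0[, 1]) + 1L
  seed_set(ijk1, label = obj$label, provenance = obj$provenance,
           min_seeds = min_seeds, max_seeds = max_seeds)
}

#' Write a segmentation report (without its mask) as JSON
#'
#' @param report A `segmentation_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(volume_ml = report$volume_ml,
         tolerance_fraction = report$tolerance_fraction,
         acceptance_window_hu = report$acceptance_window_hu,
         connectivity = report$connectivity,
         codes = report$codes,
         overspill = report$overspill[c("flag", "codes", "faces", "fraction")],
         replicate_index = report$replicate_index,
         spacing_mm = report$spacing_mm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a pipeline run configuration as YAML
#'
#' A persisted configuration re-runs to identical outputs for all
#' deterministic stages (`parse(serialise(config)) = config`).
#'
#' @param config Configuration list (see [run_config()]).
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
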