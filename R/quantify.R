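# Calibrated volumetry and cohort bookkeeping.

#' Convert a binary voxel mask to millilitres
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param spacing_mm Positive isotropic voxel spacing in mm.
#' @return Volume in mL: `voxel_count * spacing_mm^3 / 1000`.
#' @examples
#' mask_volume_ml(array(TRUE, c(10, 10, 10)), 0.1)  # 0.001 mL
#' @export
mask_volume_ml <- function(mask, spacing_mm) {
  if (!is_scalar(spacing_mm) || spacing_mm <= 0) {
    abort_input("`spacing_mm` must be positive")
  }
  sum(mask != 0) * spacing_mm^3 / 1000
}

#' Tumour burden as the inverse aerated-volume surrogate
#'
#' Tumour consolidates lung and removes it from the aerated segmentation,
#' so the fractional loss of aerated volume relative to a reference reads as
#' tumour burden: `max(0, 1 - volume_ml / reference_ml)`.
#'
#' @param volume_ml Measured aerated volume (mL).
#' @param reference_ml Positive reference aerated volume (mL); by convention
#'   the per-animal maximum observed volume (see [burden_from_cohort()]).
#' @return Burden fraction in \[0, 1\].
#' @export
tumour_burden_surrogate <- function(volume_ml, reference_ml) {
  if (any(reference_ml <= 0)) abort_input("`reference_ml` must be positive")
  pmax(0, 1 - volume_ml / reference_ml)
}

#' Add a tumour-burden column to a cohort table
#'
#' @param table Cohort `data.frame` (columns `animal_id`, `month`,
#'   `volume_ml`).
#' @param reference `"per_animal_max"` (default) or `"fixed"`.
#' @param reference_ml Reference volume when `reference = "fixed"`.
#' @return The table with an added `burden` column.
#' @export
burden_from_cohort <- function(table, reference = c("per_animal_max", "fixed"),
                               reference_ml = NULL) {
  reference <- match.arg(reference)
  if (reference == "fixed") {
    if (is.null(reference_ml)) abort_input("`reference_ml` required for fixed reference")
    ref <- rep(reference_ml, nrow(table))
  } else {
    ref <- stats::ave(table$volume_ml, table$animal_id, FUN = max)
    if (any(ref <= 0)) abort_input("per-animal maximum volume must be positive")
  }
  table$burden <- tumour_burden_surrogate(table$volume_ml, ref)
  table
}

#' Thoracic-organ to body-weight ratio
#'
#' @param organ_g,body_g Positive masses in grams.
#' @return List with `ratio` (unrounded) and `ratio_2dp` (half-up rounding
#'   to two decimals, for table reproduction).
#' @examples
#' organ_body_ratio(1.44, 36.95)$ratio_2dp  # 0.04
#' @export
organ_body_ratio <- function(organ_g, body_g) {
  if (any(organ_g <= 0) || any(body_g <= 0)) {
    abort_input("masses must be positive")
  }
  ratio <- organ_g / body_g
  list(ratio = ratio, ratio_2dp = floor(ratio * 100 + 0.5) / 100)
}

COHORT_COLUMNS <- c("animal_id", "genotype", "sex", "month", "volume_ml")

validate_cohort <- function(table) {
  if (!is.data.frame(table) || !all(COHORT_COLUMNS %in% names(table))) {
    abort_input("cohort table must have columns: ",
                paste(COHORT_COLUMNS, collapse = ", "))
  }
  if (anyDuplicated(table[, c("animal_id", "month")])) {
    abort_input("(animal_id, month) pairs must be unique")
  }
  if (any(table$volume_ml < 0)) abort_input("volumes must be >= 0")
  invisible(table)
}

#' Write / read a cohort table as CSV
#'
#' Long-format schema: `animal_id, genotype, sex, month, volume_ml`.
#' Volumes are written at full precision so the table round-trips.
#'
#' @param table Cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the validated `data.frame`.
#' @export
write_cohort_csv <- function(table, path) {
  validate_cohort(table)
  out <- table[, COHORT_COLUMNS]
  out$volume_ml <- sprintf("%.15g", out$volume_ml)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$month <- as.numeric(tab$month)
  tab$volume_ml <- as.numeric(tab$volume_ml)
  validate_cohort(tab)
  tab
}
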