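# Radiation-dose bookkeeping for repetitive micro-CT scanning.

#' Radiation dose model for repetitive scanning
#'
#' Constants of the respiratory-gated scanning protocol: the effective dose
#' of the CT protocol itself, the fluoroscopy rate for scan-area planning,
#' the resulting total per-scan dose used for cumulative sums, and the
#' expected mean dose from phantom/cadaver measurements. All in mGy.
#'
#' @param per_scan_mgy Total dose per examination including fluoroscopic
#'   planning (default 202); the constant used for cumulative arithmetic.
#' @param protocol_mgy Effective dose of the CT protocol alone (default 154).
#' @param fluoro_rate_mgy_per_min Fluoroscopy dose rate (default 19).
#' @param expected_mean_mgy Expected mean dose per scan from phantom
#'   measurements (default 197).
#' @return An object of class `dose_model`.
#' @export
dose_model <- function(per_scan_mgy = 202, protocol_mgy = 154,
                       fluoro_rate_mgy_per_min = 19, expected_mean_mgy = 197) {
  vals <- c(per_scan_mgy, protocol_mgy, fluoro_rate_mgy_per_min, expected_mean_mgy)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_input("all dose-model constants must be positive")
  }
  structure(list(per_scan_mgy = per_scan_mgy, protocol_mgy = protocol_mgy,
                 fluoro_rate_mgy_per_min = fluoro_rate_mgy_per_min,
                 expected_mean_mgy = expected_mean_mgy),
            class = "dose_model")
}

#' Cumulative radiation dose over repetitive examinations
#'
#' @param n_exams Non-negative examination count (vectorised).
#' @param model A [dose_model()].
#' @return `n_exams * per_scan_mgy`, in mGy.
#' @examples
#' cumulative_dose(4)   # 808 mGy
#' cumulative_dose(15)  # 3030 mGy
#' @export
cumulative_dose <- function(n_exams, model = dose_model()) {
  if (any(!is.finite(n_exams)) || any(n_exams < 0) || any(n_exams != round(n_exams))) {
    abort_input("`n_exams` must be non-negative integer counts")
  }
  n_exams * model$per_scan_mgy
}

#' Cohort summary of cumulative doses
#'
#' @param exam_counts Nonempty vector of per-animal examination counts.
#' @param model A [dose_model()].
#' @return List with per-animal cumulative doses (`per_animal_mgy`) and
#'   their `min_mgy`, `max_mgy`, `mean_mgy`, plus `mean_exams` and
#'   `sd_exams`.
#' @export
cohort_dose_summary <- function(exam_counts, model = dose_model()) {
  if (length(exam_counts) == 0L) abort_input("`exam_counts` must be nonempty")
  doses <- cumulative_dose(exam_counts, model)
  list(per_animal_mgy = doses,
       min_mgy = min(doses), max_mgy = max(doses), mean_mgy = mean(doses),
       mean_exams = mean(exam_counts),
       sd_exams = if (length(exam_counts) > 1L) sd(exam_counts) else NA_real_)
}
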