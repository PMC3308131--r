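# Longitudinal growth-kinetics statistics: two-way mixed (split-plot)
# repeated-measures ANOVA over selected time points, a between-group
# contrast restricted to the late tumour-progression window, and the linear
# growth model with its correlation coefficient.
#
# The ANOVA is computed from explicit sums of squares on the complete-case
# design: the between-subject SS splits into group and subject-within-group;
# the within-subject SS into time, time x group and residual. With every
# retained animal measured at every requested month the cell frequencies are
# proportional, so the decomposition is orthogonal even with unequal group
# sizes.

complete_case_filter <- function(table, timepoints) {
  table <- table[table$month %in% timepoints, , drop = FALSE]
  counts <- table(table$animal_id)
  complete <- names(counts)[counts == length(timepoints)]
  excluded <- sort(setdiff(unique(table$animal_id), complete))
  list(table = table[table$animal_id %in% complete, , drop = FALSE],
       excluded = excluded)
}

#' Repeated-measures mixed ANOVA for a longitudinal cohort
#'
#' Two-way split-plot ANOVA of `volume_ml` with a between-subject factor
#' (genotype group) and a within-subject factor (month). Animals missing any
#' requested time point are excluded (complete-case analysis, no
#' imputation); the exclusions are reported. F ratios use the split-plot
#' error terms: group against subject-within-group, time and time x group
#' against the within-subject residual. P-values are uncorrected by default;
#' Greenhouse-Geisser sphericity correction of the within-subject tests is
#' available.
#'
#' @param table Cohort `data.frame` (columns `animal_id`, `genotype`,
#'   `month`, `volume_ml`).
#' @param timepoints Months to analyse (default: all months present).
#' @param groups The two genotype levels to contrast.
#' @param sphericity_correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return An object of class `kinetics_result`: F and p for time, group and
#'   interaction, degrees of freedom, the SS table, time points used, and
#'   animals used/excluded.
#' @examples
#' tab <- simulate_cohort(4, 3, months = c(2, 4, 6), rng_seed = 7)
#' repeated_measures_anova(tab)$p_time
#' @export
repeated_measures_anova <- function(table, timepoints = NULL,
                                    groups = c("transgenic", "wildtype"),
                                    sphericity_correction = c("none", "greenhouse-geisser")) {
  sphericity_correction <- match.arg(sphericity_correction)
  if (!all(c("animal_id", "genotype", "month", "volume_ml") %in% names(table))) {
    abort_input("table must have columns animal_id, genotype, month, volume_ml")
  }
  table <- table[table$genotype %in% groups, , drop = FALSE]
  if (length(unique(table$genotype)) < 2L) {
    abort_input("both groups must be present in the table")
  }
  if (is.null(timepoints)) timepoints <- sort(unique(table$month))
  cc <- complete_case_filter(table, timepoints)
  tab <- cc$table
  if (nrow(tab) == 0L) abort_input("no complete-case animals at the requested time points")

  gmap <- unique(tab[, c("animal_id", "genotype")])
  if (anyDuplicated(gmap$animal_id)) {
    abort_input("an animal appears under two genotypes: ",
                paste(gmap$animal_id[duplicated(gmap$animal_id)], collapse = ", "))
  }
  per_group <- table(gmap$genotype)
  if (length(per_group) < 2L || any(per_group < 2L)) {
    abort_input("need >= 2 complete-case animals per group; have: ",
                paste(names(per_group), per_group, sep = "=", collapse = ", "))
  }

  T_ <- length(timepoints)
  subjects <- gmap$animal_id
  n <- length(subjects)
  y <- tab$volume_ml
  grand <- mean(y)

  subj_mean <- tapply(y, tab$animal_id, mean)[subjects]
  subj_group <- gmap$genotype
  group_mean <- tapply(y, tab$genotype, mean)
  n_g <- per_group[names(group_mean)]
  time_mean <- tapply(y, tab$month, mean)
  cell_mean <- tapply(y, list(tab$genotype, tab$month), mean)

  ss_total <- sum((y - grand)^2)
  ss_between <- T_ * sum((subj_mean - grand)^2)
  ss_group <- T_ * sum(n_g * (group_mean - grand)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- n * sum((time_mean - grand)^2)
  ss_cells <- sum(outer(n_g, rep(1, T_)) * (cell_mean - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_time
  ss_resid <- ss_total - ss_between - ss_time - ss_inter

  df <- list(group = length(n_g) - 1L, subj = n - length(n_g),
             time = T_ - 1L, inter = (length(n_g) - 1L) * (T_ - 1L))
  df$resid <- df$subj * df$time

  eps <- 1
  if (sphericity_correction == "greenhouse-geisser" && T_ > 2L) {
    # Greenhouse-Geisser epsilon from the pooled within-group covariance of
    # the subject x time matrix
    wide <- matrix(NA_real_, n, T_, dimnames = list(subjects, timepoints))
    wide[cbind(match(tab$animal_id, subjects), match(tab$month, timepoints))] <- y
    resid_wide <- wide
    for (g in rownames(cell_mean)) {
      rows <- subj_group == g
      resid_wide[rows, ] <- sweep(wide[rows, , drop = FALSE], 2, cell_mean[g, ])
    }
    S <- crossprod(resid_wide) / (n - length(n_g))
    C <- S - outer(rowMeans(S), rep(1, T_)) - outer(rep(1, T_), colMeans(S)) + mean(S)
    eps <- sum(diag(C))^2 / ((T_ - 1) * sum(C^2))
    eps <- min(1, max(eps, 1 / (T_ - 1)))
  }

  f_or_zero <- function(ss_eff, df_eff, ss_err, df_err, correct = FALSE) {
    e <- if (correct) eps else 1
    ms_eff <- ss_eff / df_eff
    ms_err <- ss_err / df_err
    if (ss_eff <= .Machine$double.eps * max(1, ss_total)) {
      return(list(F = 0, p = 1))
    }
    if (ms_err <= 0) return(list(F = Inf, p = 0))
    F_ <- ms_eff / ms_err
    list(F = F_, p = pf(F_, df_eff * e, df_err * e, lower.tail = FALSE))
  }

  time_test <- f_or_zero(ss_time, df$time, ss_resid, df$resid, correct = TRUE)
  group_test <- f_or_zero(ss_group, df$group, ss_subj, df$subj)
  inter_test <- f_or_zero(ss_inter, df$inter, ss_resid, df$resid, correct = TRUE)

  structure(
    list(F_time = time_test$F, p_time = time_test$p,
         F_group = group_test$F, p_group = group_test$p,
         F_interaction = inter_test$F, p_interaction = inter_test$p,
         df = df, epsilon = eps,
         ss = c(group = ss_group, subject = ss_subj, time = ss_time,
                interaction = ss_inter, residual = ss_resid, total = ss_total),
         timepoints = timepoints,
         animals_used = sort(subjects), animals_excluded = cc$excluded,
         n_per_group = as.list(per_group)),
    class = "kinetics_result"
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("<kinetics_result> repeated-measures mixed ANOVA\n")
  cat(sprintf("  time:        F(%d,%d) = %.3f, p = %.4g\n",
              x$df$time, x$df$resid, x$F_time, x$p_time))
  cat(sprintf("  group:       F(%d,%d) = %.3f, p = %.4g\n",
              x$df$group, x$df$subj, x$F_group, x$p_group))
  cat(sprintf("  interaction: F(%d,%d) = %.3f, p = %.4g\n",
              x$df$inter, x$df$resid, x$F_interaction, x$p_interaction))
  if (length(x$animals_excluded)) {
    cat("  excluded (incomplete follow-up):",
        paste(x$animals_excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Between-group contrast over a late time window
#'
#' Runs the mixed ANOVA restricted to months inside `window` (default 8-13,
#' the window of marked tumour progression) and returns the between-subject
#' group p-value.
#'
#' @param table Cohort `data.frame`.
#' @param window Length-2 numeric month window (inclusive).
#' @param ... Passed to [repeated_measures_anova()].
#' @return Scalar p-value for the group effect, with the full
#'   `kinetics_result` attached as attribute `"result"`.
#' @export
group_difference_window <- function(table, window = c(8, 13), ...) {
  months <- sort(unique(table$month))
  months <- months[months >= window[1] & months <= window[2]]
  if (length(months) < 2L) {
    abort_input("fewer than two time points fall inside the window")
  }
  res <- repeated_measures_anova(table, timepoints = months, ...)
  structure(res$p_group, result = res)
}

#' Fit the linear lung-volume growth model
#'
#' Ordinary least squares of aerated volume on `(month - 1)`:
#' `volume_ml = intercept_ml + slope_ml_per_month * (month - 1)`.
#' The correlation coefficient R is reported unsigned (absolute Pearson
#' correlation of month and volume).
#'
#' @param table Cohort `data.frame`.
#' @param genotype Rows to fit: `"transgenic"` (default, the tumour-bearing
#'   group whose decline the model describes), `"wildtype"`, or `"all"`
#'   (groups pooled).
#' @return An object of class `regression_fit`: `slope_ml_per_month`,
#'   `intercept_ml`, `R`, `n_points`.
#' @examples
#' tab <- data.frame(animal_id = "a1", genotype = "transgenic", sex = "F",
#'                   month = 1:5, volume_ml = 0.315 - 0.01 * (1:5 - 1))
#' fit_linear_kinetics(tab)
#' @export
fit_linear_kinetics <- function(table, genotype = "transgenic") {
  if (genotype != "all") {
    table <- table[table$genotype == genotype, , drop = FALSE]
  }
  if (nrow(table) < 3L) abort_input("need >= 3 rows to fit the growth model")
  if (length(unique(table$month)) < 2L) {
    abort_input("all months identical; the growth model is undefined")
  }
  fit <- lm(volume_ml ~ I(month - 1), data = table)
  r <- abs(cor(table$month, table$volume_ml))
  structure(
    list(slope_ml_per_month = unname(coef(fit)[2]),
         intercept_ml = unname(coef(fit)[1]),
         R = r, n_points = nrow(table)),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> volume = %.4f %+.4f x (month - 1) mL; R = %.3f (n = %d)\n",
    x$intercept_ml, x$slope_ml_per_month, x$R, x$n_points))
  invisible(x)
}
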