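# End-to-end orchestration of the longitudinal workflow:
# simulate -> segment -> quantify -> kinetics -> dose.

#' Default pipeline run configuration
#'
#' Returns the fully-serialisable configuration list consumed by
#' [run_pipeline()]; persist it with [write_run_config()]. Defaults are
#' desk-scale (a small grid and micro-cohort) so a full run completes in
#' well under a minute.
#'
#' @param out_dir Output directory for all artefacts.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "segment", "quantify", "kinetics", "dose")`; `"all"`
#'   expands to every stage.
#' @param rng_seed Master seed; stage seeds are derived from it.
#' @param n_transgenic,n_wildtype,months Cohort design.
#' @param grid_shape,spacing_mm,noise_sd_hu Phantom rendering settings.
#' @param n_seeds,tolerance_fraction,connectivity,prefilter Segmentation
#'   protocol settings.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir = "results/pipeline",
                       stages = "all",
                       rng_seed = 1L,
                       n_transgenic = 2L, n_wildtype = 2L,
                       months = c(2, 3, 4),
                       grid_shape = c(64L, 64L, 64L),
                       spacing_mm = 0.2, noise_sd_hu = 0,
                       n_seeds = 20L, tolerance_fraction = 0.02,
                       connectivity = 6L, prefilter = "none") {
  all_stages <- c("simulate", "segment", "quantify", "kinetics", "dose")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages)) {
    abort_input("unknown stage(s): ",
                paste(setdiff(stages, all_stages), collapse = ", "))
  }
  structure(list(
    out_dir = out_dir, stages = stages, rng_seed = as.integer(rng_seed),
    cohort = list(n_transgenic = as.integer(n_transgenic),
                  n_wildtype = as.integer(n_wildtype),
                  months = as.numeric(months)),
    phantom = list(grid_shape = as.integer(grid_shape),
                   spacing_mm = spacing_mm, noise_sd_hu = noise_sd_hu),
    segmentation = list(n_seeds = as.integer(n_seeds),
                        tolerance_fraction = tolerance_fraction,
                        connectivity = as.integer(connectivity),
                        prefilter = prefilter)
  ), class = c("run_config", "list"))
}

pipeline_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the longitudinal quantification pipeline
#'
#' Executes the requested stages in order. `simulate` writes per-scan
#' phantom NIfTI volumes (with companion label grids) and the ground-truth
#' cohort CSV; `segment` runs the triplicate region-growing protocol on
#' every scan; `quantify` assembles the measured cohort CSV with the
#' inverse-burden surrogate; `kinetics` writes the repeated-measures ANOVA
#' and linear growth fit; `dose` writes the cumulative-dose summary. Every
#' stage logs its parameters and seeds; a stage failure aborts with the
#' stage name and cause.
#'
#' @param config A [run_config()] (or a list with the same shape, e.g. read
#'   back from YAML).
#' @return Invisibly, a named list of artefact paths per stage.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  artefacts <- list()
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    pipeline_log(log_path, stage, sprintf("start (seed %d)", config$rng_seed))
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    pipeline_log(log_path, stage, "done")
    artefacts[[stage]] <<- res
  }

  growth <- growth_params()
  scan_dir <- file.path(config$out_dir, "scans")
  true_csv <- file.path(config$out_dir, "cohort_true.csv")

  run_stage("simulate", function() {
    dir.create(scan_dir, showWarnings = FALSE)
    tab <- simulate_cohort(config$cohort$n_transgenic, config$cohort$n_wildtype,
                           months = config$cohort$months, growth = growth,
                           rng_seed = config$rng_seed)
    write_cohort_csv(tab, true_csv)
    paths <- character(0)
    ref <- growth$plateau_ml
    for (row in seq_len(nrow(tab))) {
      burden <- min(0.95, tumour_burden_surrogate(tab$volume_ml[row], ref))
      spec <- phantom_spec(grid_shape = config$phantom$grid_shape,
                           spacing_mm = config$phantom$spacing_mm,
                           noise_sd_hu = config$phantom$noise_sd_hu,
                           rng_seed = config$rng_seed + row)
      ph <- make_thorax_phantom(spec, burden)
      stem <- file.path(scan_dir, sprintf("%s_m%02d", tab$animal_id[row],
                                          round(tab$month[row])))
      write_hu_nifti(ph$volume, paste0(stem, ".nii.gz"))
      write_label_nifti(ph$truth$compartment_labels, spec$spacing_mm,
                        paste0(stem, "_labels.nii.gz"))
      paths <- c(paths, paste0(stem, ".nii.gz"))
    }
    list(cohort_true = true_csv, volumes = paths)
  })

  seg_csv <- file.path(config$out_dir, "segmented_volumes.csv")
  run_stage("segment", function() {
    scans <- list.files(scan_dir, pattern = "_m[0-9]+\\.nii\\.gz$",
                        full.names = TRUE)
    if (length(scans) == 0L) abort_input("no scans found; run the simulate stage first")
    rows <- lapply(seq_along(scans), function(s) {
      vol <- read_hu_nifti(scans[s])
      trip <- triplicate_volume(
        vol,
        seeding = list(n_seeds = config$segmentation$n_seeds,
                       hu_window = c(-900, -300), min_separation_mm = 0.5,
                       rng_seed = config$rng_seed + 10L * s),
        tolerance_fraction = config$segmentation$tolerance_fraction,
        connectivity = config$segmentation$connectivity,
        prefilter = config$segmentation$prefilter)
      stem <- sub("\\.nii\\.gz$", "", basename(scans[s]))
      parts <- strsplit(stem, "_m")[[1]]
      for (r in 1:3) {
        write_report_json(trip$replicates[[r]],
                          file.path(scan_dir, sprintf("%s_rep%d.json", stem, r)))
      }
      data.frame(animal_id = parts[1], month = as.numeric(parts[2]),
                 mean_volume_ml = trip$mean_volume_ml,
                 sd_volume_ml = trip$sd_volume_ml,
                 quality_flag = trip$quality_flag,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    write.csv(out, seg_csv, row.names = FALSE)
    seg_csv
  })

  measured_csv <- file.path(config$out_dir, "cohort_measured.csv")
  run_stage("quantify", function() {
    seg <- read.csv(seg_csv, stringsAsFactors = FALSE)
    truth <- read_cohort_csv(true_csv)
    tab <- merge(truth[, c("animal_id", "genotype", "sex", "month")], seg,
                 by = c("animal_id", "month"))
    tab$volume_ml <- tab$mean_volume_ml
    tab <- burden_from_cohort(tab[, COHORT_COLUMNS])
    write.csv(tab, measured_csv, row.names = FALSE)
    measured_csv
  })

  run_stage("kinetics", function() {
    src <- if (file.exists(measured_csv)) measured_csv else true_csv
    tab <- read.csv(src, stringsAsFactors = FALSE)
    anova_res <- repeated_measures_anova(tab)
    fit <- fit_linear_kinetics(tab)
    out <- file.path(config$out_dir, "kinetics.json")
    jsonlite::write_json(
      list(source = src,
           anova = anova_res[c("F_time", "p_time", "F_group", "p_group",
                               "F_interaction", "p_interaction",
                               "timepoints", "animals_used", "animals_excluded")],
           fit = fit[c("slope_ml_per_month", "intercept_ml", "R", "n_points")]),
      out, auto_unbox = TRUE, digits = NA)
    out
  })

  run_stage("dose", function() {
    n_scans <- length(config$cohort$months)
    n_animals <- config$cohort$n_transgenic + config$cohort$n_wildtype
    summary <- cohort_dose_summary(rep(n_scans, n_animals))
    out <- file.path(config$out_dir, "dose.json")
    jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA)
    out
  })

  invisible(artefacts)
}
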