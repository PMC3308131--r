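#!/usr/bin/env Rscript
# Triplicate region-growing segmentation of the phantom series written by
# 01_simulate.R: grows the aerated lung from 30 automatically placed seeds
# with the 2%-of-range tolerance, averages three replicates per scan, and
# compares against ground truth. Noisy scans are median-denoised first.
# Also demonstrates overspill: seeds dropped into the open airway leak to
# the volume border and are repaired by repositioning.

library(aerolung)

scans <- list.files("results/scans", pattern = "_noise[0-9]+\\.nii\\.gz$",
                    full.names = TRUE)
if (length(scans) == 0) stop("run analysis/01_simulate.R first")

rows <- list()
for (path in scans) {
  vol <- read_hu_nifti(path)
  labs <- read_label_nifti(sub("\\.nii\\.gz$", "_labels.nii.gz", path))
  truth_ml <- mask_volume_ml(labs == 1, attr(labs, "spacing_mm"))
  noisy <- grepl("noise40", path)
  trip <- triplicate_volume(vol,
                            seeding = list(n_seeds = 30L,
                                           hu_window = c(-900, -300),
                                           min_separation_mm = 0.5,
                                           rng_seed = 1L),
                            prefilter = if (noisy) "median" else "none")
  rel_err <- (trip$mean_volume_ml - truth_ml) / truth_ml
  rows[[length(rows) + 1]] <- data.frame(
    scan = basename(path), truth_ml = truth_ml,
    mean_ml = trip$mean_volume_ml, sd_ml = trip$sd_volume_ml,
    rel_err = rel_err, quality_flag = trip$quality_flag)
  cat(sprintf("%-22s truth %.3f mL  measured %.3f mL  error %+.2f%%\n",
              basename(path), truth_ml, trip$mean_volume_ml, 100 * rel_err))
}
out <- do.call(rbind, rows)
write.csv(out, "results/segmentation_recovery.csv", row.names = FALSE)
cat("\nNote: at late-stage burden the residual aerated lung fragments into\n",
    "pockets isolated by confluent tumour; region growing recovers only the\n",
    "seeded connected portion, so noisy late-stage volumes are biased low.\n",
    "Longitudinal burden reads therefore use the relative decline per animal\n",
    "rather than absolute late-stage accuracy.\n", sep = "")

cat("\n-- overspill demonstration --\n")
ph <- make_thorax_phantom(phantom_spec(noise_sd_hu = 0, rng_seed = 101), 0.35)
bad <- auto_place_seeds(ph$volume, 10, hu_window = c(-1005, -995), rng_seed = 5)
rep1 <- region_grow(ph$volume, bad)
cat("airway-seeded growth:", paste(rep1$overspill$codes, collapse = ", "),
    sprintf("(%.0f%% of grid)\n", 100 * rep1$overspill$fraction))
fixed <- reposition_seeds(bad, rep1, ph$volume, rng_seed = 6)
rep2 <- region_grow(ph$volume, fixed)
cat(sprintf("after repositioning: overspill = %s, error vs truth %+.2f%%\n",
            rep2$overspill$flag,
            100 * (rep2$volume_ml - ph$truth$aerated_volume_ml) /
              ph$truth$aerated_volume_ml))
write_report_json(rep2, "results/overspill_repaired_report.json")
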