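#!/usr/bin/env Rscript
# Cumulative radiation-dose bookkeeping for the repetitive scanning
# protocol: per-scan dose of 202 mGy (154 mGy CT protocol + fluoroscopic
# scan planning at 19 mGy/min), monthly follow-up of 4 to 15 exams.

library(aerolung)

model <- dose_model()
cat(sprintf("dose model: %g mGy/scan (protocol %g mGy, fluoroscopy %g mGy/min)\n",
            model$per_scan_mgy, model$protocol_mgy, model$fluoro_rate_mgy_per_min))

# follow-up as realised in a 12-animal cohort totalling 156 exams
exam_counts <- c(13, 12, 15, 14, 14, 14, 15, 15, 15, 14, 11, 4)
stopifnot(sum(exam_counts) == 156)
s <- cohort_dose_summary(exam_counts, model)
cat(sprintf("exams/animal: mean %.1f (SD %.2f)\n", s$mean_exams, s$sd_exams))
cat(sprintf("cumulative dose: %g to %g mGy, mean %g mGy\n",
            s$min_mgy, s$max_mgy, s$mean_mgy))
cat(sprintf("check: 4 exams = %g mGy, 13 = %g mGy, 15 = %g mGy\n",
            cumulative_dose(4), cumulative_dose(13), cumulative_dose(15)))

jsonlite::write_json(s, "results/dose.json", auto_unbox = TRUE, digits = NA)
cat("written: results/dose.json\n")
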