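#!/usr/bin/env Rscript
# Descriptive comparison of the three sampling strategies on the same
# latent cohort, plus the published-count arithmetic for the three field
# datasets (printed denominators, detect/exceedance fractions, and the
# manhole-entry contrast). Requires results/cohort/ from
# analysis/01_simulate_cohort.R.

library(h2sindex)

out_dir <- "results/compare"
datasets <- lapply(c(A = "A", B = "B", C = "C"), function(l)
  read_study_dataset(file.path("results/cohort", paste0("dataset_", l))))

res <- run_compare(datasets, out_dir)
cat("Synthetic-cohort strategy comparison:\n")
print(res$summary[, c("label", "n_measured", "pct_detect_of_measured",
                      "pct_cv_of_measured", "pct_cv_of_detect")])

# the published field-study counts, recomputed
published <- rbind(
  summary_from_counts("A", 93, 25, 8, 1, 35, 149, 19),
  summary_from_counts("B", 7083, 1295, 424, 3, 1559, 60, 66),
  summary_from_counts("C", 872, 522, 118, 0, 60, 60, 7,
                      frame_workdays = 1807))
write.csv(published, file.path(out_dir, "published_counts_summary.csv"),
          row.names = FALSE)
cat("\nPublished-count arithmetic (field datasets):\n")
print(published[, c("label", "study_workdays", "duration_workdays",
                    "pct_detect_of_measured", "pct_cv_of_measured",
                    "pct_cv_of_detect")])

manholes <- data.frame(
  contrast = c("uncorrected", "group-size corrected"),
  ratio = c(round_half_up(manhole_entry_ratio(34, 15, 3, 24, corrected = FALSE)),
            round_half_up(manhole_entry_ratio(34, 15, 3, 24, corrected = TRUE))))
write.csv(manholes, file.path(out_dir, "manhole_ratios.csv"), row.names = FALSE)
cat("\nManhole-entry contrast (water vs wastewater network):\n")
print(manholes)
cat("\nOutputs written to", out_dir, "\n")
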