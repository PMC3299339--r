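#!/usr/bin/env Rscript
# Recompute each scan's corrected implant density from its printed anchors
# via the per-scan two-point correction, and compare with the printed
# corrected column.
# Writes: results/corrected_comparison.csv

library(orbcal)

res <- run_study_reanalysis(run_config())
rec <- res$records

dir.create("results", showWarnings = FALSE)
write.csv(rec[, c("id_label", "oi_mean_hu", "cv_mean_hu", "dv_max_hu",
                  "corrected_mean_hu", "corrected_recomputed_hu",
                  "delta_hu", "delta_pct")],
          "results/corrected_comparison.csv", row.names = FALSE)

cat(sprintf(
  "Recomputed vs printed corrected HU over 30 records:\n  mean |delta| %.2f HU (%.2f%%), max |delta| %.2f HU (record %s)\n",
  mean(abs(rec$delta_hu)), mean(abs(rec$delta_pct)),
  max(abs(rec$delta_hu)), rec$id_label[which.max(abs(rec$delta_hu))]))
cat("The residual deviations are consistent with the printed column having\n",
    "been computed from unrounded per-scan inputs that the table does not\n",
    "carry; they are reported, never asserted.\n", sep = "")
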