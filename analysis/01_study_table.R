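#!/usr/bin/env Rscript
# Load the packaged 30-implant CBCT table and summarise the cohort.
# Writes: results/study_table.csv, results/cohort_summary.csv

library(orbcal)

tab <- load_study_table()
s <- summarize_cohort(tab)

dir.create("results", showWarnings = FALSE)
write_records(tab, "results/study_table.csv")
write.csv(data.frame(
  n_records = s$n_records,
  lifespan_min_days = s$lifespan_min_days,
  lifespan_max_days = s$lifespan_max_days,
  lifespan_mean_days = s$lifespan_mean_days,
  diameter_deviation_sd_mm = s$diameter_deviation_sd_mm
), "results/cohort_summary.csv", row.names = FALSE)

print(s)
cat(sprintf(
  "Direct summation gives a mean lifespan of %.1f days over all 30 records\n",
  s$lifespan_mean_days))
cat(sprintf(
  "Record 1.26 carries flag '%s' (printed factory diameter 10 mm vs 19.66 mm estimate)\n",
  tab$quality_flags[tab$id_label == "1.26"]))
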