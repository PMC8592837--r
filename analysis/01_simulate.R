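#!/usr/bin/env Rscript
# Simulate the study cohort: 64 tumour patients (one TMA core each, IT + PT
# regions) plus 11 normal-tissue controls, with H&E lymphocyte flags and a
# 10-marker mIHC panel. Cell-level tables are large and go to scratch/;
# small summaries go to results/.

suppressPackageStartupMessages(library(immunotopo))

dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(n_patients = 64, n_controls = 11, seed = 1L)
cohort <- generate_cohort(cfg)
print(cohort)

write_cell_table(cohort$cells, "scratch/cohort/cells.csv")
write_table_csv(cohort$clinical, "scratch/cohort/clinical.csv")
write_table_csv(cohort$mutations, "scratch/cohort/mutations.csv")
write_table_csv(cohort$truth$patients, "scratch/cohort/truth_patients.csv")

write_table_csv(
  data.frame(table(topography = cohort$truth$patients$topography)),
  "results/simulated_topography_truth.csv")

cat(sprintf("cells: %d rows; clinical: %d patients; mutations: %d genes\n",
            nrow(cohort$cells), nrow(cohort$clinical),
            ncol(cohort$mutations) - 1))
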