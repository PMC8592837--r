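#!/usr/bin/env Rscript
# Immune topography assignment and downstream association screens:
# core-level cellularity filter, per-region lymphocyte proportions,
# two-phase hot/cold/excluded clustering, mutation association per class,
# and the survival contrast of the excluded topography.

suppressPackageStartupMessages(library(immunotopo))

cells <- read_cell_table("scratch/cohort/cells.csv", flavor = "hne")
clinical <- read_clinical_table("scratch/cohort/clinical.csv")
mutations <- read_mutation_table("scratch/cohort/mutations.csv")
truth <- read.csv("scratch/cohort/truth_patients.csv")

filt <- filter_low_cellularity(cells, min_cells = 1500)
cat(sprintf("cellularity filter: %d of %d cores dropped\n",
            length(filt$dropped), length(unique(cells$core_id))))

props <- region_lymphocyte_proportion(filt$cells)
cat(sprintf("median lymphocyte proportion: IT %.1f%%, PT %.1f%%\n",
            100 * median(props$proportion[props$region == "IT"]),
            100 * median(props$proportion[props$region == "PT"])))

topo <- assign_topographies(topography_input(props))
write_table_csv(topo, "results/topography.csv")
summ <- topography_summary(topo)
write_table_csv(summ, "results/topography_summary.csv")
print(summ)

merged <- merge(topo, truth, by = "patient_id")
cat(sprintf("agreement with generating truth: %.1f%%\n",
            100 * mean(as.character(merged$label) == merged$topography)))

for (cls in c("hot", "cold", "excluded")) {
  assoc <- mutation_topography_association(topo, mutations, target_class = cls)
  write_table_csv(assoc, sprintf("results/mutation_association_%s.csv", cls))
  top <- assoc[1, ]
  cat(sprintf("%-8s top gene %-6s OR %.2f p %.3g (%s)\n",
              cls, top$gene, top$odds_ratio, top$p_value, top$test_used))
}

surv_in <- merge(clinical, topo[, c("patient_id", "label")], by = "patient_id")
res <- cox_survival(as.numeric(surv_in$label == "excluded"), surv_in,
                    dichotomize = FALSE)
res$feature <- "topography_excluded"
write_table_csv(res, "results/survival_topography.csv")
cat(sprintf("excluded topography OS: HR %.2f (%.3f-%.2f), log-rank p %.3g\n",
            res$hr, res$ci_low, res$ci_high, res$logrank_p))
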