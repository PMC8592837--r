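#!/usr/bin/env Rscript
# mIHC phenotype profiling: automatic bimodal gating, multi-label cell
# classification, the patient-by-phenotype proportion matrix with
# heatmap normalization and Spearman/Ward.D2 clustering, IT-PT phenotype
# correlation, and topography fold-change panels.

suppressPackageStartupMessages(library(immunotopo))

cells <- read_cell_table("scratch/cohort/cells.csv", flavor = "mihc")
topo <- read.csv("results/topography.csv")
markers <- attr(cells, "markers")

pos <- gate_cells(cells, as.list(setNames(rep("auto", length(markers)), markers)))
cat("auto thresholds:\n"); print(round(attr(pos, "thresholds"), 2))
cls <- classify_cell_types(pos)
gc <- gated_cohort(cells, pos, cls)

mat <- build_phenotype_matrix(gc)
write_table_csv(mat, "results/phenotype_matrix.csv")
write_table_csv(attr(mat, "contexture"), "results/phenotype_contexture.csv")
norm <- normalize_for_heatmap(mat)
write_table_csv(norm, "results/phenotype_matrix_normalized.csv")

pheno_cols <- attr(mat, "phenotypes")
col_cl <- cluster_profiles(t(as.matrix(mat[pheno_cols])))
cat("phenotype clustering leaf order:\n")
print(pheno_cols[col_cl$order])

corr <- correlate_it_pt(mat, groups = list(
  t_cell = grep("^(T|helper_T|cytotoxic_T)", pheno_cols, value = TRUE),
  nk = grep("^NK", pheno_cols, value = TRUE)))
write_table_csv(corr, "results/it_pt_correlation.csv")
cat(sprintf("median IT-PT Spearman rho: %.2f (T-cell %.2f, NK %.2f)\n",
            median(corr$rho, na.rm = TRUE),
            attr(corr, "group_medians")["t_cell"],
            attr(corr, "group_medians")["nk"]))

it <- mat[mat$region == "IT", ]
it <- merge(it, topo[, c("patient_id", "label")], by = "patient_id")
panel <- group_fc_panel(it[, c("patient_id", pheno_cols)], it$label)
write_table_csv(panel, "results/topography_fc_panel_it.csv")
cat(sprintf("topography FC panel (IT): %d significant feature-class pairs\n",
            sum(panel$p_value < 0.05, na.rm = TRUE)))
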