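#!/usr/bin/env Rscript
# Spatial interaction analysis: the normalized interaction index I_ab for
# all class pairs per patient and region, regional contrasts, the
# interaction-conditioned phenotype fold-change screen for T cells
# interacting with NK cells, and a digital staining figure.

suppressPackageStartupMessages(library(immunotopo))

cells <- read_cell_table("scratch/cohort/cells.csv", flavor = "mihc")
markers <- attr(cells, "markers")
pos <- gate_cells(cells, as.list(setNames(rep("auto", length(markers)), markers)))
gc <- gated_cohort(cells, pos, classify_cell_types(pos))

cfg <- interaction_config()
cat(sprintf("interaction radius: %d px = %.0f um\n", cfg$threshold_px, cfg$threshold_um))

im <- interaction_matrix(gc, cfg)
write_table_csv(im, "results/interactions.csv")
for (reg in c("IT", "PT", "CTRL"))
  cat(sprintf("%-4s median I_ab %.1f across %d records\n", reg,
              median(im$index[im$region == reg], na.rm = TRUE),
              sum(im$region == reg)))
tn <- im[im$type_a == "NK" & im$type_b == "T" |
         im$type_a == "T" & im$type_b == "NK", ]
cmp <- compare_groups(tn$index[tn$region %in% c("IT", "PT")],
                      tn$region[tn$region %in% c("IT", "PT")])
cat(sprintf("T-NK index IT vs PT: log10 FC %.2f, rank-sum p %.3g\n",
            cmp$log10_fc, cmp$p_value))

fc <- interaction_phenotype_fc(gc, "T", "NK",
                               c("PD1", "LAG3", "TIM3", "CD45RO", "GrB"), cfg)
write_table_csv(fc, "results/interaction_fc_T_NK.csv")
print(fc[fc$region == "IT", c("marker", "n_patients", "log10_fc", "p_value", "q_value")])

dir.create("scratch/figures", recursive = TRUE, showWarnings = FALSE)
one <- gc[gc$patient_id == "P001", ]
out <- digital_stain(one, phenotype_def("T", "TIM3"),
                     "scratch/figures/digital_stain_TIM3_T_P001.png")
cat(sprintf("digital stain written (%d cells, %d phenotype-positive)\n",
            attr(out, "n_points"), attr(out, "n_positive")))
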