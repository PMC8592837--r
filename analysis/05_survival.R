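#!/usr/bin/env Rscript
# Survival biomarker screen: every phenotype proportion (median-
# dichotomized, IT and PT separately) against overall survival with
# univariate Cox regression and BH correction across the screen.

suppressPackageStartupMessages(library(immunotopo))

clinical <- read_clinical_table("scratch/cohort/clinical.csv")
mat <- read.csv("results/phenotype_matrix.csv", check.names = FALSE)
pheno_cols <- setdiff(colnames(mat), c("patient_id", "region"))

rows <- list()
for (reg in c("IT", "PT")) {
  sub <- merge(clinical, mat[mat$region == reg, c("patient_id", pheno_cols)],
               by = "patient_id")
  for (ph in pheno_cols) {
    res <- tryCatch(cox_survival(sub[[ph]], sub, dichotomize = TRUE),
                    error = function(e) NULL)
    if (is.null(res)) next
    res$feature <- ph; res$region <- reg
    rows[[paste(reg, ph)]] <- res
  }
}
screen <- do.call(rbind, rows)
rownames(screen) <- NULL
screen$q_value <- NA_real_
ok <- !is.na(screen$logrank_p)
screen$q_value[ok] <- adjust_bh(screen$logrank_p[ok])
screen <- screen[order(screen$logrank_p), ]
write_table_csv(screen, "results/survival_screen.csv")

cat(sprintf("screened %d region-phenotype features; %d with log-rank p < 0.05\n",
            nrow(screen), sum(screen$logrank_p < 0.05, na.rm = TRUE)))
print(head(screen[, c("region", "feature", "hr", "ci_low", "ci_high",
                      "logrank_p", "q_value")], 5))
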