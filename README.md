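# immunotopo

Spatial immunoprofiling of tumour tissue from per-cell histology
coordinates, for researchers analysing digitised H&E and multiplex
immunohistochemistry (mIHC) tissue-microarray data with separately
annotated intratumoral (IT) and peritumoral (PT) regions — the setting of
clear cell renal cell carcinoma nephrectomy cohorts.

The workflow covers:

* **Immune topography** — per patient, lymphocyte proportions are computed
  per region and patients are classified *hot* / *cold* / *excluded* by
  two-phase unsupervised clustering (Ward.D2, Euclidean distance): phase 1
  on the IT proportion defines hot; phase 2 on `delta = PT − IT` separates
  excluded from cold among the rest.
* **Mutation association** — per gene 2×2 tables (topography class vs.
  rest × mutated vs. wild-type) tested with chi-square (Yates) when all
  cells exceed 5 and Fisher's exact test otherwise, BH-corrected.
* **Phenotyping** — bimodal-midpoint ("auto") or fixed gating of marker
  intensities, multi-label classes (T = CD3+, helper T = CD3+CD4+,
  cytotoxic T = CD3+CD8+, NK = CD2+CD3−, myeloid = CD16+), and
  patient×region phenotype-proportion matrices with median-centre /
  max-scale normalization and Spearman-distance Ward.D2 clustering.
* **Spatial interaction** — cells within 100 px (22 µm at 0.22 µm/px)
  interact; for types *a*, *b* with *m*, *n* cells among *c* total, the
  pair count `i_ab` is normalized to the index

  `I_ab = i_ab / (sqrt(m·n) / c)`

  which removes the dependence on type abundance. Phenotypes of
  interacting vs. non-interacting cells are contrasted as
  `log10(median p_int / median p_non)` with paired Wilcoxon tests across
  patients.
* **Clinical association** — median-dichotomized features, rank-sum /
  Kruskal–Wallis panels, and univariate Cox survival screens (HR, Wald CI,
  log-rank p).
* **Synthetic cohorts** — a generator with per-patient topography truth,
  clustered (Thomas-type) point patterns, class-linked bimodal marker
  intensities, topography-linked mutation odds and proportional-hazards
  survival, used by the test suite for parameter-recovery checks.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated 64-patient cohort (plus 11 normal-tissue controls, ≈280,000
cells, 10 markers), writing tables to `results/` and bulky cell-level
data to `scratch/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_topography.R
Rscript analysis/03_phenotypes.R
Rscript analysis/04_interactions.R
Rscript analysis/05_survival.R
```

`02_topography.R` prints, for the default seed:

```
median lymphocyte proportion: IT 3.6%, PT 6.7%
     label  n percent
1      hot 17    26.6
2     cold 38    59.4
3 excluded  9    14.1
agreement with generating truth: 100.0%
cold     top gene PBRM1  OR 5.29 p 0.00436 (chisq)
excluded top gene VHL    OR 0.07 p 0.00315 (fisher)
excluded topography OS: HR 0.11 (0.015-0.87), log-rank p 0.014
```

Reading: peritumoral infiltration exceeds intratumoral at the cohort
level; the two-phase clustering recovers every generated topography
label; the mutation screen finds the generated associations (PBRM1
enriched in cold tumours, VHL depleted in excluded ones); and the
excluded topography carries the generated survival advantage (hazard
ratio 0.11). `04_interactions.R` reports the 22 µm interaction radius,
per-region median interaction indexes and the interaction-conditioned
phenotype fold-change screen for T cells interacting with NK cells.

The same operations are available directly:

```r
library(immunotopo)
cohort <- generate_cohort(cohort_config(n_patients = 64, seed = 1))
props  <- region_lymphocyte_proportion(cohort$cells)
topo   <- assign_topographies(topography_input(props))
topography_summary(topo)
mutation_topography_association(topo, cohort$mutations, "cold")
```

## Input formats

CSV with header, UTF-8, `.` decimal, empty field = missing.

* **Cell table** (`read_cell_table`): `cell_id`, `patient_id`, `core_id`,
  `region` (IT/PT/CTRL), `x_px`, `y_px`, plus `is_lymphocyte` (H&E) and/or
  one column per marker intensity (mIHC). Unknown columns are preserved.
* **Clinical table** (`read_clinical_table`): `patient_id`, `os_time`
  (days), `os_event` (0/1), optional stage/grade/metastasis/MSKCC/age
  columns.
* **Mutation table** (`read_mutation_table`): `patient_id` plus one
  binary column per gene (empty = missing call).

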