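---
title: "Methods: spatial immune topography and cell-interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune topography and cell-interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`immunotopo` analyses per-cell tables derived from digitised tumour tissue:
each detected cell carries a patient, a tissue-microarray core, a region
label (intratumoral `IT`, peritumoral `PT`, or normal-tissue control
`CTRL`), planar pixel coordinates, and either an H&E-derived lymphocyte
flag or a panel of multiplex-immunohistochemistry (mIHC) marker
intensities. Coordinates are pixels at a physical scale of 0.22 µm/pixel by
default; all spatial computation happens in pixels and the scale is used
only to report physical distances. Cores with fewer than 1500 cells
(counted across all regions of the core) are removed before analysis,
because sparse cores make both proportions and spatial statistics
unstable; `filter_low_cellularity()` can instead be applied per
core-region via a flag.

# Immune topography classification

Per patient and region, the lymphocyte proportion is the lymphocyte count
over the total cell count. Patients are assigned a topography in two
unsupervised phases, each an agglomerative hierarchical clustering
(Euclidean distance, Ward.D2 linkage) of a one-dimensional feature cut
into two clusters:

1. **Hot** — clustering of the IT lymphocyte proportion; the cluster with
   the higher mean is hot.
2. **Excluded vs. cold** — clustering of `delta = PT − IT` proportion
   restricted to non-hot patients; the higher-mean-delta cluster is
   excluded, the other cold.

Two conventions are design choices of this package, since cluster→label
mapping is otherwise undefined: labels follow cluster means, and exact
mean ties resolve to cold (the conservative class). Correlation-based
distances are undefined on one-dimensional features, so Euclidean distance
is used in both phases; the same Spearman-distance/Ward.D2 combination
used for heatmaps is available where profiles are multivariate
(`cluster_profiles()`). Degenerate all-equal inputs raise an error by
default (`on_degenerate = "all_cold"` opts into a fallback). On
well-separated 1-D data, the Ward.D2 cut coincides with the
minimum-within-variance split, which the test suite checks against a
brute-force all-splits minimiser.

The assignment is invariant to row permutation and to adding a constant to
all proportions; it is *not* invariant to rescaling, which changes
relative gaps.

# Mutation association

For a target topography class, each gene mutated in ≥5 % of labelled
patients is tested on the 2×2 table (class vs. rest) × (mutated vs.
wild-type), dropping missing calls pairwise per gene. Dispatch: chi-square
with Yates continuity correction when every observed cell exceeds 5,
otherwise the two-sided Fisher exact test; `test_override` forces either
path, and every result records `test_used`. The Yates correction is used
because the corrected statistic is the conventional choice for single 2×2
tables at these sample sizes. P-values are Benjamini–Hochberg adjusted
across genes.

# Gating and phenotypes

A cell is positive for a marker when its intensity is **≥** the threshold
(the boundary counts as positive; the convention is arbitrary and stated
here once). `"auto"` thresholds fit a two-component Gaussian mixture to
log intensities (`mclust`, unequal variances) and gate at the midpoint of
the component means; when the component gap is below 4 RMS within-SDs the
distribution is declared unimodal — a single Gaussian split in two shows a
gap of only ≈2.7 — and the midpoint of the observed range is used with a
warning.

Cell classes are boolean rules over positivity (T = CD3+, helper T =
CD3+CD4+, cytotoxic T = CD3+CD8+, NK = CD2+CD3−, myeloid = CD16+). Classes
overlap, so classification is multi-label and subset consistency
(cytotoxic T ⊆ T) holds by construction. Phenotype proportions are either
relative to all cells or to the parent class; parent-class denominators
below 10 cells (configurable) yield a missing value to avoid unstable
ratios.

Heatmap normalization is per feature (column): median-centre, then divide
by the maximum absolute centred value, so every column lies in [−1, 1]
with constant columns mapped to zero. Per-feature normalization is chosen
because phenotype proportions span orders of magnitude. Profile clustering
uses 1 − Spearman ρ as distance with Ward.D2; constant rows, whose
correlation is undefined, are appended unclustered. An alternative —
Euclidean distance between rows of the Spearman correlation matrix — is
available as `distance = "euclidean_cor"`.

# Interaction index

Cells within 100 px (22 µm) interact; the cutoff is inclusive. For types
*a*, *b* with *m*, *n* cells among *c* total cells in one patient-region,
the interaction frequency `i_ab` counts interacting pairs and the
normalized index is

\[ I_{ab} = \frac{i_{ab}}{\sqrt{mn}/c} = \frac{i_{ab}\,c}{\sqrt{mn}}. \]

The normalising quantity is the geometric-mean pair proportion
\(\sqrt{mn}/c\), which removes the dependence of raw pair counts on type
abundance; a variant using \(\sqrt{m+n}/c\) is available through
`interaction_config(normalization = "sum")`. Conventions:

* same-type pairs are unordered with self-pairs excluded (a double sum
  over j,k would count each cell's zero self-distance);
* a cell carrying two overlapping class labels never pairs with itself —
  pairs are excluded by `cell_id`;
* pairs never span regions, patients or cores; with multiple cores per
  patient, `i_ab`, `m`, `n`, `c` are summed across cores before the index
  is formed;
* `I_ab` is missing when either type is absent (m = 0 or n = 0).

Pair counting uses a grid partition with bin width equal to the threshold
(only 3×3 neighbourhoods are scanned) and is required by the test suite to
agree exactly with the O(mn) brute-force double loop.

For interaction-conditioned phenotypes, a focal cell is *interacting* when
at least one distinct partner-type cell lies within the threshold. Per
patient, marker-positive proportions are computed separately for
interacting and non-interacting focal cells (both groups must have ≥10
cells); the fold change is `log10` of the ratio of across-patient medians,
tested with the two-sided paired Wilcoxon signed-rank test across patients
and BH-adjusted across the markers of a screen. Medians are taken across
patients rather than pooling cells, so large cores cannot dominate the
contrast.

# Group comparison and survival

Two groups of a continuous feature are compared with the unpaired
two-sided Wilcoxon rank-sum test, three or more with Kruskal–Wallis; the
paired signed-rank test is reserved for the interacting/non-interacting
contrast, which is paired within patients. Clinical variables are
dichotomized at the median with ties assigned to the low class
(configurable). Survival screens are univariate Cox proportional-hazards
fits on overall survival reporting the hazard ratio, Wald 95 % CI and the
score (log-rank) p-value; Kaplan–Meier coordinates are attached for
plotting. Preconditions (≥10 patients, ≥3 events) guard against
meaningless fits, and non-convergence is flagged rather than hidden.

# The synthetic cohort generator

No per-cell data are deposited with the study this workflow models, so
the generator is the package's test bed: it emulates the *structure* the
analysis assumes and returns the generating truth for recovery scoring.

* **Topographies** are drawn with weights (hot 0.22, cold 0.59, excluded
  0.19), matching the reported class distribution of a 64-patient ccRCC
  cohort; one 2-region core per patient, with optional control patients
  and a `cores_per_patient` flag.
* **Lymphocyte fractions** are beta-distributed per patient with
  topography/region-specific means (hot IT 0.25 / PT 0.18; cold
  0.03 / 0.06; excluded 0.04 / 0.20; control 0.02) and concentration 400
  (patient-to-patient SD ≈ 2 % at a mean of 0.2). Means are deliberately
  well separated so that label-recovery failures indicate algorithmic
  regressions, not overlapping truth.
* **Positions** are uniform or a Thomas-type cluster process (Poisson
  parents, Gaussian-displaced Poisson offspring, uniform background);
  offspring outside the region rectangle are clipped. Cluster membership
  is recorded per cell, and marker positivity can be enriched among
  cluster cells (`cluster_enrichment`) to create interaction-linked
  phenotype signal.
* **Markers** follow a two-mode log-normal intensity mixture (negative
  mode at log 1, positive at log 12, SD 0.35 — a ≈7 SD separation, so
  midpoint gating is near-perfect by design and gating failures are
  informative). Class-conditional positivity probabilities link lineage
  markers to true classes.
* **Mutations** are Bernoulli per gene with topography odds ratios on the
  logit scale (PBRM1 enriched in cold, BAP1 in excluded, STAG2 in hot,
  VHL depleted in excluded).
* **Survival** is exponential-baseline proportional hazards with named
  log-hazard coefficients (default: excluded topography log 0.2,
  per-metastasis 0.15) and independent exponential censoring calibrated
  to a target null censoring fraction.

The random stream is split per patient from the cohort seed, so the same
configuration is byte-identical across calls and enlarging the cohort
never perturbs existing patients.

What the generator does **not** emulate: segmentation artefacts, staining
batch effects, spatially varying density within a region, irregular
region shapes, correlated marker noise, or informative censoring. Passing
recovery tests therefore demonstrate correctness of the computations
under the stated statistical structure, not robustness to real-data
artefacts.

# Problem sizes and numerical choices

The packaged simulations use cohorts of 64 patients at 250 cells/region
(label recovery, 50 replicates), 16 patients at 500 cells/region
(gating, matrices, interactions), n = 500 per Cox fit (11 replicates,
median reported), and 40 patients at 1200 IT cells for the
interaction-conditioned fold-change power analysis (20 replicates) —
sizes at which every recovery metric is stable to the few-percent level.
The analysis drivers under `analysis/` run the full-density cohort
(2000 cells/region, 64 + 11 patients, ≈280k cells) in a few minutes.

Tie-breaking and degeneracy rules are stated where they occur: inclusive
gating and interaction thresholds, median ties to the low class, cluster
ties to cold, all-zero heatmap columns to zero, missing indices when a
type is absent. Probabilities after cluster enrichment are capped at
0.95. All hierarchical clustering is deterministic given the input order;
`stats::hclust` resolves distance ties by merge index.

# Known limitations

* The two-phase clustering requires ≥4 patients and non-degenerate
  spread; it always produces two phase-1 clusters even when the cohort
  has no hot tumours, so tiny or unusual cohorts deserve inspection of
  the underlying proportions.
* The interaction index is undefined for absent types and noisy for very
  rare ones; no permutation-null calibration is attempted because the
  index is defined directly, not as an enrichment statistic.
* Auto-gating assumes a two-mode intensity structure; markers with
  genuinely continuous expression need manual thresholds.
* Survival screens are univariate by design; no multivariable model
  selection is provided.
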