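## Synthetic-cohort configuration ------------------------------------------
##
## The generator emulates a TMA-based spatial immunoprofiling study: one core
## per patient with manually separated intratumoral (IT) and peritumoral (PT)
## regions, per-cell coordinates in pixels, an H&E-style lymphocyte flag, and
## an mIHC-style marker-intensity panel. Ground truth (topography labels,
## per-cell class and marker positivity, survival coefficients) is returned
## alongside the tables so recovery tests can score the analysis.

#' Default per-topography lymphocyte-fraction parameters
#'
#' Beta-distributed per-patient lymphocyte fractions for each immune
#' topography and tissue region. Means are well separated by construction:
#' hot tumours are infiltrated intratumorally, excluded tumours only
#' peritumorally, cold tumours nowhere, and control (normal) tissue carries a
#' small resident fraction. `concentration` is the beta a+b sum; 400 gives a
#' patient-to-patient SD of about 0.02 at a mean of 0.2.
#'
#' @return A data.frame with columns `topography`, `region`, `mean`,
#'   `concentration`.
#' @export
default_lymph_params <- function() {
  data.frame(
    topography    = c("hot", "hot", "cold", "cold", "excluded", "excluded", "control"),
    region        = c("IT",  "PT",  "IT",   "PT",   "IT",       "PT",       "CTRL"),
    mean          = c(0.25,  0.18,  0.03,   0.06,   0.04,       0.20,       0.02),
    concentration = rep(400, 7),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic mIHC marker panel
#'
#' Lineage markers (CD3, CD4, CD8, CD2, CD16) carry class-dependent
#' positivity probabilities; phenotype markers (PD1, LAG3, TIM3, CD45RO, GrB)
#' carry activation/exhaustion-like base rates. Intensities are drawn from a
#' two-mode log-normal mixture; the positive mode sits ~7 within-mode SDs
#' above the negative mode so midpoint gating is near-perfect by design.
#' `cluster_enrichment` multiplies the positivity probability for cells that
#' belong to a spatial cluster (capped at 0.95), used to emulate
#' interaction-linked phenotype enrichment.
#'
#' @return Named list of per-marker parameter lists.
#' @export
default_marker_panel <- function() {
  mk <- function(helper_T, cytotoxic_T, NK, myeloid, other, cluster_enrichment = 1) {
    list(
      pos_prob = c(helper_T = helper_T, cytotoxic_T = cytotoxic_T, NK = NK,
                   myeloid = myeloid, other = other),
      neg_meanlog = 0, pos_meanlog = log(12), sdlog = 0.35,
      cluster_enrichment = cluster_enrichment
    )
  }
  list(
    CD3    = mk(0.98, 0.98, 0.01, 0.01, 0.01),
    CD4    = mk(0.95, 0.03, 0.02, 0.25, 0.02),
    CD8    = mk(0.03, 0.95, 0.25, 0.02, 0.02),
    CD2    = mk(0.90, 0.90, 0.98, 0.02, 0.02),
    CD16   = mk(0.02, 0.02, 0.20, 0.95, 0.01),
    PD1    = mk(0.20, 0.25, 0.08, 0.02, 0.01),
    LAG3   = mk(0.08, 0.12, 0.05, 0.01, 0.01),
    TIM3   = mk(0.10, 0.12, 0.10, 0.05, 0.01),
    CD45RO = mk(0.35, 0.30, 0.05, 0.02, 0.01),
    GrB    = mk(0.05, 0.30, 0.35, 0.02, 0.01)
  )
}

#' Default somatic-mutation model
#'
#' Per-gene baseline prevalence with per-topography odds ratios, emulating
#' ccRCC driver-gene frequencies and their reported topography associations
#' (PBRM1 enriched in cold, BAP1 in excluded, STAG2 in hot tumours; VHL
#' depleted in excluded tumours).
#'
#' @return Named list of per-gene lists with `prevalence` and `or`.
#' @export
default_mutation_model <- function() {
  gene <- function(prev, hot = 1, cold = 1, excluded = 1)
    list(prevalence = prev, or = c(hot = hot, cold = cold, excluded = excluded))
  list(
    VHL   = gene(0.62, excluded = 0.35),
    PBRM1 = gene(0.43, cold = 2.8),
    SETD2 = gene(0.12),
    BAP1  = gene(0.10, excluded = 2.5, hot = 0.4),
    STAG2 = gene(0.06, hot = 4.0),
    KDM5C = gene(0.07),
    MTOR  = gene(0.06),
    TP53  = gene(0.05)
  )
}

#' Build a validated synthetic-cohort configuration
#'
#' @param n_patients Number of tumour patients (one TMA core each).
#' @param n_controls Number of control patients contributing normal renal
#'   tissue cores (region `CTRL`).
#' @param topography_weights Probability triple (hot, cold, excluded);
#'   must sum to 1.
#' @param region_geometry Named list of rectangles
#'   `c(xmin, xmax, ymin, ymax)` in pixels for regions IT, PT and CTRL.
#'   IT and PT must not overlap.
#' @param cell_density Named expected cell counts per core per region.
#' @param lymph_fraction_params Data frame as [default_lymph_params()].
#' @param spatial_process List with `type` ("uniform" or "clustered") and,
#'   for the clustered Thomas-type process, `mean_offspring` (cells per
#'   cluster), `cluster_radius` (Gaussian dispersion SD, pixels) and
#'   `background_fraction` (share of cells from the uniform background).
#' @param marker_panel Named list as [default_marker_panel()], or `NULL` to
#'   skip marker simulation (H&E-only cohorts are much faster to generate).
#' @param lymph_class_probs,nonlymph_class_probs Class composition of
#'   lymphocyte and non-lymphocyte cells.
#' @param mutation_model Named list as [default_mutation_model()].
#' @param survival_model List with `baseline_rate` (events/day under an
#'   exponential baseline), named `coefficients` (log-hazard scale, matched
#'   to generated covariates `topography_excluded`, `topography_hot`,
#'   `age_z`, `n_metastatic_organs`) and `censoring_rate` (target fraction
#'   censored under the null).
#' @param cores_per_patient Number of TMA cores per patient.
#' @param pixel_size_um Physical pixel size, micrometres per pixel.
#' @param seed Integer seed; the cohort stream is split per patient so
#'   adding patients does not perturb earlier ones.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 64,
                          n_controls = 0,
                          topography_weights = c(hot = 0.22, cold = 0.59, excluded = 0.19),
                          region_geometry = list(
                            IT   = c(xmin = 0,    xmax = 3000, ymin = 0, ymax = 3000),
                            PT   = c(xmin = 3200, xmax = 6200, ymin = 0, ymax = 3000),
                            CTRL = c(xmin = 0,    xmax = 3000, ymin = 0, ymax = 3000)
                          ),
                          cell_density = c(IT = 2000, PT = 2000, CTRL = 2000),
                          lymph_fraction_params = default_lymph_params(),
                          spatial_process = list(type = "uniform",
                                                 mean_offspring = 40,
                                                 cluster_radius = 60,
                                                 background_fraction = 0.5),
                          marker_panel = default_marker_panel(),
                          lymph_class_probs = c(helper_T = 0.40, cytotoxic_T = 0.35, NK = 0.25),
                          nonlymph_class_probs = c(other = 0.94, myeloid = 0.06),
                          mutation_model = default_mutation_model(),
                          survival_model = list(
                            baseline_rate = 1 / 1500,
                            coefficients = c(topography_excluded = log(0.2),
                                             n_metastatic_organs = 0.15),
                            censoring_rate = 0.35
                          ),
                          cores_per_patient = 1,
                          pixel_size_um = 0.22,
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1)
    config_error("n_patients", "must be a positive count")
  if (n_controls < 0) config_error("n_controls", "must be nonnegative")
  w <- topography_weights
  if (length(w) != 3 || any(is.na(w)) || any(w < 0))
    config_error("topography_weights", "must be three nonnegative probabilities")
  if (abs(sum(w) - 1) > 1e-9)
    config_error("topography_weights", sprintf("must sum to 1 (got %.12f)", sum(w)))
  if (is.null(names(w))) names(w) <- c("hot", "cold", "excluded")
  for (r in names(region_geometry)) {
    g <- region_geometry[[r]]
    if ((g["xmax"] - g["xmin"]) <= 0 || (g["ymax"] - g["ymin"]) <= 0)
      config_error("region_geometry", sprintf("region %s has non-positive area", r))
  }
  git <- region_geometry[["IT"]]; gpt <- region_geometry[["PT"]]
  if (!is.null(git) && !is.null(gpt)) {
    overlap_x <- min(git["xmax"], gpt["xmax"]) > max(git["xmin"], gpt["xmin"])
    overlap_y <- min(git["ymax"], gpt["ymax"]) > max(git["ymin"], gpt["ymin"])
    if (overlap_x && overlap_y)
      config_error("region_geometry", "IT and PT rectangles overlap")
  }
  if (any(!is.finite(cell_density)) || any(cell_density <= 0))
    config_error("cell_density", "densities must be strictly positive")
  lf <- lymph_fraction_params
  if (any(lf$mean <= 0 | lf$mean >= 1) || any(lf$concentration <= 0))
    config_error("lymph_fraction_params", "means must lie in (0,1), concentrations be positive")
  if (!spatial_process$type %in% c("uniform", "clustered"))
    config_error("spatial_process", "type must be 'uniform' or 'clustered'")
  if (!is.null(marker_panel)) {
    for (m in names(marker_panel)) {
      p <- marker_panel[[m]]
      if (any(p$pos_prob < 0 | p$pos_prob > 1))
        config_error("marker_panel", sprintf("%s positivity probabilities outside [0,1]", m))
      if (p$pos_meanlog <= p$neg_meanlog)
        config_error("marker_panel", sprintf("%s mixture modes not ordered (positive mode must exceed negative)", m))
    }
  }
  for (g in names(mutation_model)) {
    pm <- mutation_model[[g]]
    if (pm$prevalence <= 0 || pm$prevalence >= 1)
      config_error("mutation_model", sprintf("%s prevalence outside (0,1)", g))
    if (any(pm$or <= 0)) config_error("mutation_model", sprintf("%s odds ratios must be positive", g))
  }
  sm <- survival_model
  if (sm$baseline_rate <= 0) config_error("survival_model", "baseline_rate must be positive")
  if (sm$censoring_rate < 0 || sm$censoring_rate > 1)
    config_error("survival_model", "censoring_rate must lie in [0,1]")
  if (pixel_size_um <= 0) config_error("pixel_size_um", "must be positive")

  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    topography_weights = w, region_geometry = region_geometry,
    cell_density = cell_density, lymph_fraction_params = lf,
    spatial_process = spatial_process, marker_panel = marker_panel,
    lymph_class_probs = lymph_class_probs / sum(lymph_class_probs),
    nonlymph_class_probs = nonlymph_class_probs / sum(nonlymph_class_probs),
    mutation_model = mutation_model, survival_model = sm,
    cores_per_patient = as.integer(cores_per_patient),
    pixel_size_um = pixel_size_um, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}
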