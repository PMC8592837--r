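# Shared fixtures, built in code.

# Small all-purpose cohort with markers; memoised per test run.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(
        n_patients = 16,
        cell_density = c(IT = 500, PT = 500, CTRL = 500),
        seed = 42
      ))
    }
    cache
  }
})

# Fast H&E-only configuration for label-recovery simulations.
recovery_config <- function(seed, n_patients = 64, density = 250) {
  cohort_config(
    n_patients = n_patients,
    cell_density = c(IT = density, PT = density, CTRL = density),
    marker_panel = NULL,
    seed = seed
  )
}

# Reduced-panel class rules matching fc_scenario_config().
fc_rules <- c(T = "CD3", NK = "CD2 & !CD3")

# Scenario for the interaction-conditioned fold-change power analysis:
# clustered cell positions, with CD45RO positivity enriched 3-fold among
# cells belonging to a spatial cluster. T and NK cells co-cluster, so
# T cells interacting with NK cells are predominantly cluster members.
fc_scenario_config <- function(seed, n_patients = 40) {
  mk <- function(helper_T, cytotoxic_T, NK, myeloid, other, enr = 1) {
    list(pos_prob = c(helper_T = helper_T, cytotoxic_T = cytotoxic_T, NK = NK,
                      myeloid = myeloid, other = other),
         neg_meanlog = 0, pos_meanlog = log(12), sdlog = 0.35,
         cluster_enrichment = enr)
  }
  cohort_config(
    n_patients = n_patients,
    topography_weights = c(hot = 1, cold = 0, excluded = 0),
    cell_density = c(IT = 1200, PT = 60, CTRL = 60),
    spatial_process = list(type = "clustered", mean_offspring = 40,
                           cluster_radius = 60, background_fraction = 0.5),
    lymph_class_probs = c(helper_T = 0.35, cytotoxic_T = 0.30, NK = 0.35),
    marker_panel = list(
      CD3    = mk(0.98, 0.98, 0.01, 0.01, 0.01),
      CD2    = mk(0.90, 0.90, 0.98, 0.02, 0.02),
      CD45RO = mk(0.10, 0.10, 0.05, 0.02, 0.01, enr = 3)
    ),
    seed = seed
  )
}

# Gate a cohort at the known inter-mode midpoint (log-scale midpoint of
# the default mixture) and classify it.
gate_and_classify <- function(cohort, rules = default_class_rules()) {
  markers <- names(cohort$config$marker_panel)
  thr <- as.list(setNames(rep(sqrt(12), length(markers)), markers))
  pos <- gate_cells(cohort$cells, thr)
  cls <- classify_cell_types(pos, rules)
  gated_cohort(cohort$cells, pos, cls)
}

# Hand-built minimal cell table.
toy_cells <- function() {
  data.frame(
    cell_id = sprintf("c%02d", 1:6),
    patient_id = rep(c("P1", "P2"), each = 3),
    core_id = rep(c("P1_core1", "P2_core1"), each = 3),
    region = c("IT", "IT", "PT", "IT", "PT", "PT"),
    x_px = c(0, 60, 200, 10, 20, 30),
    y_px = c(0, 80, 200, 10, 20, 30),
    is_lymphocyte = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
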