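## End-to-end pipeline orchestration ---------------------------------------

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full spatial-immunoprofiling pipeline
#'
#' Executes core filtering, topography assignment, mutation association,
#' phenotype profiling, interaction analysis and the survival screen, and
#' writes all result tables plus a provenance JSON to `output_dir`. Inputs
#' are either CSV paths (`mode = "files"`) or a simulation specification
#' (`mode = "simulate"`), in which case one synthetic cohort provides both
#' the H&E and mIHC flavours.
#'
#' @param config A list or a YAML file path. Recognised fields:
#'   `mode` ("simulate"/"files"); `simulate` (arguments to
#'   [cohort_config()]); `inputs` (paths `cells`, `clinical`, `mutations`);
#'   `min_cells` (core filter, default 1500); `interaction` (arguments to
#'   [interaction_config()]); `target_class` (mutation association class,
#'   default "cold"); `output_dir`.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir %||% stop("pipeline stage 'config' failed: output_dir missing", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  data <- run_stage("load", {
    if (identical(config$mode %||% "simulate", "simulate")) {
      cohort <- generate_cohort(do.call(cohort_config, config$simulate %||% list()))
      list(cells = cohort$cells, clinical = cohort$clinical,
           mutations = cohort$mutations, cohort = cohort)
    } else {
      inputs <- config$inputs
      for (f in c("cells", "clinical", "mutations"))
        if (is.null(inputs[[f]]) || !file.exists(inputs[[f]]))
          stop("missing input path: ", f)
      list(cells = read_cell_table(inputs$cells, flavor = "mihc"),
           clinical = read_clinical_table(inputs$clinical),
           mutations = read_mutation_table(inputs$mutations))
    }
  })

  filt <- run_stage("filter", {
    filter_low_cellularity(data$cells, min_cells = config$min_cells %||% 1500)
  })
  cells <- filt$cells

  topo <- run_stage("topography", {
    props <- region_lymphocyte_proportion(cells)
    assign_topographies(topography_input(props))
  })
  write_table_csv(topo, file.path(out_dir, "topography.csv"))

  mut_assoc <- run_stage("mutation_association", {
    mutation_topography_association(topo, data$mutations,
                                    target_class = config$target_class %||% "cold")
  })
  write_table_csv(mut_assoc, file.path(out_dir, "mutation_association.csv"))

  pheno <- run_stage("phenotype", {
    markers <- attr(data$cells, "markers") %||%
      setdiff(colnames(cells), c(CELL_BASE_COLS, "is_lymphocyte", "panel_id"))
    gating <- as.list(setNames(rep("auto", length(markers)), markers))
    pos <- gate_cells(cells, gating)
    cls <- classify_cell_types(pos)
    gc <- gated_cohort(cells, pos, cls)
    mat <- build_phenotype_matrix(gc)
    list(gc = gc, matrix = mat, normalized = normalize_for_heatmap(mat))
  })
  write_table_csv(pheno$matrix, file.path(out_dir, "phenotype_matrix.csv"))
  write_table_csv(pheno$normalized, file.path(out_dir, "phenotype_matrix_normalized.csv"))

  inter <- run_stage("interaction", {
    interaction_matrix(pheno$gc, do.call(interaction_config, config$interaction %||% list()))
  })
  write_table_csv(inter, file.path(out_dir, "interactions.csv"))

  surv <- run_stage("survival", {
    merged <- merge(data$clinical, topo[, c("patient_id", "label")], by = "patient_id")
    res <- cox_survival(as.numeric(merged$label == "excluded"), merged,
                        dichotomize = FALSE)
    res$feature <- "topography_excluded"
    res
  })
  write_table_csv(surv, file.path(out_dir, "survival_excluded.csv"))

  write_provenance(file.path(out_dir, "provenance.json"), list(
    mode = config$mode %||% "simulate",
    seed = (config$simulate %||% list())$seed %||% NA,
    n_cells_in = nrow(data$cells), n_cells_kept = nrow(cells),
    dropped_cores = as.list(filt$dropped),
    min_cells = config$min_cells %||% 1500
  ))
  invisible(out_dir)
}
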