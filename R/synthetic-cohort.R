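## Synthetic cohort generation ---------------------------------------------

#' Sample a planar point pattern for one tissue region
#'
#' Points are drawn inside a rectangle either uniformly or from a
#' Thomas-type parent--offspring cluster process: Poisson-distributed parent
#' points scattered uniformly, each with a Poisson number of offspring
#' displaced by an isotropic Gaussian of SD `cluster_radius`, plus a uniform
#' background component. Offspring falling outside the rectangle are
#' discarded (edge clipping), so the realised count is slightly below the
#' nominal intensity when clusters straddle the boundary.
#'
#' Uses the current R random stream; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param n_expected Expected number of points (Poisson intensity).
#' @param geometry Rectangle `c(xmin, xmax, ymin, ymax)` in pixels.
#' @param process List with `type` ("uniform"/"clustered") and, when
#'   clustered, `mean_offspring`, `cluster_radius`, `background_fraction`.
#' @return data.frame with columns `x`, `y` and logical `clustered`
#'   (TRUE for offspring of a cluster parent).
#' @export
sample_point_pattern <- function(n_expected, geometry, process = list(type = "uniform")) {
  w <- geometry["xmax"] - geometry["xmin"]
  h <- geometry["ymax"] - geometry["ymin"]
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0)
    stop("point-pattern geometry must have positive area", call. = FALSE)
  if (n_expected < 0) stop("n_expected must be nonnegative", call. = FALSE)
  if (n_expected == 0)
    return(data.frame(x = numeric(0), y = numeric(0), clustered = logical(0)))

  runif_rect <- function(n) data.frame(
    x = runif(n, geometry["xmin"], geometry["xmax"]),
    y = runif(n, geometry["ymin"], geometry["ymax"])
  )

  if (identical(process$type, "uniform")) {
    n <- rpois(1, n_expected)
    pts <- runif_rect(n)
    pts$clustered <- rep(FALSE, n)
    rownames(pts) <- NULL
    return(pts)
  }

  bf <- process$background_fraction %||% 0.5
  mo <- process$mean_offspring %||% 40
  cr <- process$cluster_radius %||% 60
  n_bg <- rpois(1, n_expected * bf)
  bg <- runif_rect(n_bg)
  bg$clustered <- rep(FALSE, n_bg)
  n_parents <- rpois(1, n_expected * (1 - bf) / mo)
  if (n_parents > 0) {
    parents <- runif_rect(n_parents)
    n_off <- rpois(n_parents, mo)
    px <- rep(parents$x, n_off); py <- rep(parents$y, n_off)
    off <- data.frame(x = px + rnorm(length(px), 0, cr),
                      y = py + rnorm(length(py), 0, cr))
    keep <- off$x >= geometry["xmin"] & off$x <= geometry["xmax"] &
            off$y >= geometry["ymin"] & off$y <= geometry["ymax"]
    off <- off[keep, , drop = FALSE]
    off$clustered <- rep(TRUE, nrow(off))
    pts <- rbind(bg, off)
  } else {
    pts <- bg
  }
  rownames(pts) <- NULL
  pts
}

#' Sample marker intensities from a two-mode log-normal mixture
#'
#' Cells flagged positive draw from the high (positive) mode, the rest from
#' the low (negative) mode. Modes must be ordered: the positive location
#' parameter must exceed the negative one.
#'
#' @param true_positivity Logical vector of per-cell truth.
#' @param mixture List with `neg_meanlog`, `pos_meanlog`, `sdlog`.
#' @return Strictly positive intensity vector, same length as the input.
#' @export
sample_marker_intensities <- function(true_positivity, mixture) {
  if (mixture$pos_meanlog <= mixture$neg_meanlog)
    stop("intensity mixture modes not ordered: positive mode location must exceed negative",
         call. = FALSE)
  n <- length(true_positivity)
  if (n == 0) return(numeric(0))
  meanlog <- ifelse(true_positivity, mixture$pos_meanlog, mixture$neg_meanlog)
  rlnorm(n, meanlog = meanlog, sdlog = mixture$sdlog)
}

#' Sample proportional-hazards survival outcomes
#'
#' Event times follow an exponential baseline with the hazard multiplied by
#' `exp(X beta)` (a proportional-hazards structure). Independent exponential
#' censoring is calibrated so that, under the null, approximately
#' `censoring_rate` of patients are censored; `censoring_rate = 1` censors
#' everyone.
#'
#' @param covariates data.frame or matrix of covariates; columns must cover
#'   the names of `model$coefficients`.
#' @param model List with `baseline_rate`, named `coefficients`,
#'   `censoring_rate`.
#' @return data.frame with `time` (strictly positive) and `event` (0/1).
#' @export
sample_survival <- function(covariates, model) {
  covariates <- as.data.frame(covariates)
  beta <- model$coefficients
  if (length(beta) > 0) {
    missing_cov <- setdiff(names(beta), colnames(covariates))
    if (length(missing_cov) > 0)
      stop("survival coefficients refer to absent covariates: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    lp <- as.numeric(as.matrix(covariates[, names(beta), drop = FALSE]) %*% beta)
  } else {
    lp <- rep(0, nrow(covariates))
  }
  rate <- model$baseline_rate * exp(lp)
  t_event <- rexp(nrow(covariates), rate = rate)
  cr <- model$censoring_rate
  if (cr >= 1) {
    t_cens <- rexp(nrow(covariates), rate = model$baseline_rate)
    return(data.frame(time = t_cens, event = rep(0L, nrow(covariates))))
  }
  if (cr <= 0) return(data.frame(time = t_event, event = rep(1L, nrow(covariates))))
  rate_c <- model$baseline_rate * cr / (1 - cr)
  t_cens <- rexp(nrow(covariates), rate = rate_c)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

## Draw one patient's cells for one region of one core.
simulate_region_cells <- function(cfg, patient_id, core_id, region, lymph_frac) {
  geom <- cfg$region_geometry[[region]]
  pts <- sample_point_pattern(cfg$cell_density[[region]], geom, cfg$spatial_process)
  n <- nrow(pts)
  if (n == 0) return(NULL)
  is_lymph <- runif(n) < lymph_frac
  cls <- character(n)
  nl <- sum(is_lymph)
  if (nl > 0)
    cls[is_lymph] <- sample(names(cfg$lymph_class_probs), nl, replace = TRUE,
                            prob = cfg$lymph_class_probs)
  if (nl < n)
    cls[!is_lymph] <- sample(names(cfg$nonlymph_class_probs), n - nl, replace = TRUE,
                             prob = cfg$nonlymph_class_probs)
  cells <- data.frame(
    cell_id = sprintf("%s_%s_%s_%05d", patient_id, core_id, region, seq_len(n)),
    patient_id = patient_id, core_id = core_id, region = region,
    x_px = pts$x, y_px = pts$y, is_lymphocyte = is_lymph,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(cell_id = cells$cell_id, true_class = cls,
                      clustered = pts$clustered, stringsAsFactors = FALSE)
  if (!is.null(cfg$marker_panel)) {
    for (m in names(cfg$marker_panel)) {
      mp <- cfg$marker_panel[[m]]
      p <- unname(mp$pos_prob[cls])
      enr <- mp$cluster_enrichment %||% 1
      if (enr != 1) p <- ifelse(pts$clustered, pmin(p * enr, 0.95), p)
      pos <- runif(n) < p
      truth[[paste0(m, "_pos")]] <- pos
      cells[[m]] <- sample_marker_intensities(pos, mp)
    }
  }
  list(cells = cells, truth = truth)
}

#' Generate a synthetic spatial-immunoprofiling cohort
#'
#' Produces per-cell, clinical and mutation tables with the statistical
#' structure the downstream pipeline assumes -- topography-dependent IT/PT
#' lymphocyte fractions (beta-distributed), optionally clustered point
#' patterns, class-linked bimodal marker intensities, topography-linked
#' mutation odds and covariate-linked proportional-hazards survival --
#' together with the generating ground truth.
#'
#' The random stream is split per patient from `config$seed`, so two calls
#' with the same configuration are identical and extending `n_patients`
#' does not perturb the patients already generated.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with elements `cells`,
#'   `clinical`, `mutations`, `truth` (patient- and cell-level ground
#'   truth) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  cfg <- config
  lf <- cfg$lymph_fraction_params
  lf_get <- function(topo, region) lf[lf$topography == topo & lf$region == region, ]

  topo_levels <- c("hot", "cold", "excluded")
  cell_parts <- list(); truth_parts <- list(); clin_parts <- list(); mut_parts <- list()
  patient_truth <- list()

  sim_patient <- function(idx, patient_id, is_control) {
    set.seed(derive_seed(cfg$seed, idx))
    if (is_control) {
      topo <- "control"
      regions <- "CTRL"
    } else {
      topo <- sample(topo_levels, 1, prob = cfg$topography_weights[topo_levels])
      regions <- c("IT", "PT")
    }
    fr <- vapply(regions, function(r) {
      pr <- lf_get(topo, r)
      rbeta(1, pr$mean * pr$concentration, (1 - pr$mean) * pr$concentration)
    }, numeric(1))
    names(fr) <- regions
    pc <- list(); pt <- list()
    for (core in seq_len(cfg$cores_per_patient)) {
      core_id <- sprintf("%s_core%d", patient_id, core)
      for (r in regions) {
        part <- simulate_region_cells(cfg, patient_id, core_id, r, fr[[r]])
        if (!is.null(part)) { pc[[length(pc) + 1]] <- part$cells; pt[[length(pt) + 1]] <- part$truth }
      }
    }
    out <- list(cells = do.call(rbind, pc), cell_truth = do.call(rbind, pt),
                topography = topo,
                it_frac_true = unname(fr["IT"])[1] %||% NA_real_,
                pt_frac_true = unname(fr["PT"])[1] %||% NA_real_)
    if (!is_control) {
      nmet <- rpois(1, if (topo == "excluded") 0.4 else 1.2)
      mskcc <- if (topo == "excluded")
        sample(c("low", "intermediate"), 1, prob = c(0.4, 0.6))
      else sample(c("low", "intermediate", "high"), 1, prob = c(0.18, 0.64, 0.18))
      age <- rnorm(1, 65, 9)
      clin <- data.frame(
        patient_id = patient_id,
        tumor_stage = sample(1:4, 1, prob = c(0.13, 0.14, 0.25, 0.48)),
        fuhrman_grade = sample(1:4, 1, prob = c(0.06, 0.39, 0.45, 0.09)),
        n_metastatic_organs = nmet, mskcc_class = mskcc,
        age_years = age,
        tumor_size = rlnorm(1, log(60), 0.4),
        necrosis = runif(1) < 0.3,
        stringsAsFactors = FALSE
      )
      covars <- data.frame(
        topography_excluded = as.integer(topo == "excluded"),
        topography_hot = as.integer(topo == "hot"),
        age_z = (age - 65) / 9,
        n_metastatic_organs = nmet
      )
      surv <- sample_survival(covars, cfg$survival_model)
      clin$os_time <- surv$time
      clin$os_event <- surv$event
      out$clinical <- clin
      muts <- vapply(names(cfg$mutation_model), function(g) {
        pm <- cfg$mutation_model[[g]]
        p <- plogis(qlogis(pm$prevalence) + log(pm$or[[topo]]))
        as.integer(runif(1) < p)
      }, integer(1))
      out$mutations <- data.frame(patient_id = patient_id, t(muts),
                                  stringsAsFactors = FALSE)
    }
    out
  }

  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%03d", i)
    res <- sim_patient(i, pid, is_control = FALSE)
    cell_parts[[i]] <- res$cells; truth_parts[[i]] <- res$cell_truth
    clin_parts[[i]] <- res$clinical; mut_parts[[i]] <- res$mutations
    patient_truth[[i]] <- data.frame(
      patient_id = pid, topography = res$topography,
      it_frac_true = res$it_frac_true, pt_frac_true = res$pt_frac_true,
      stringsAsFactors = FALSE
    )
  }
  if (cfg$n_controls > 0) {
    for (j in seq_len(cfg$n_controls)) {
      pid <- sprintf("C%03d", j)
      res <- sim_patient(cfg$n_patients + j, pid, is_control = TRUE)
      k <- length(cell_parts) + 1
      cell_parts[[k]] <- res$cells; truth_parts[[k]] <- res$cell_truth
      patient_truth[[length(patient_truth) + 1]] <- data.frame(
        patient_id = pid, topography = "control",
        it_frac_true = NA_real_, pt_frac_true = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }

  cells <- do.call(rbind, cell_parts); rownames(cells) <- NULL
  clinical <- do.call(rbind, clin_parts); rownames(clinical) <- NULL
  mutations <- do.call(rbind, mut_parts); rownames(mutations) <- NULL
  cell_truth <- do.call(rbind, truth_parts); rownames(cell_truth) <- NULL

  structure(list(
    cells = cells, clinical = clinical, mutations = mutations,
    truth = list(
      patients = do.call(rbind, patient_truth),
      cells = cell_truth,
      survival_coefficients = cfg$survival_model$coefficients,
      mutation_model = cfg$mutation_model
    ),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic spatial-immunoprofiling cohort: %d patients, %d cells (%s markers)\n",
    length(unique(x$truth$patients$patient_id)), nrow(x$cells),
    if (is.null(x$config$marker_panel)) "no" else length(x$config$marker_panel)
  ))
  print(table(x$truth$patients$topography))
  invisible(x)
}
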