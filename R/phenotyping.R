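## Marker gating, cell classification and phenotype matrices ---------------

#' Default cell-class rules
#'
#' Boolean rules over marker positivity defining the canonical immune
#' classes: T (CD3+), helper T (CD3+CD4+), cytotoxic T (CD3+CD8+),
#' NK (CD2+CD3-) and CD16+ myeloid cells. Classes overlap by construction
#' (every cytotoxic T cell is a T cell), so classification is multi-label.
#'
#' @return Named character vector of boolean expressions over markers.
#' @export
default_class_rules <- function() {
  c(T           = "CD3",
    helper_T    = "CD3 & CD4",
    cytotoxic_T = "CD3 & CD8",
    NK          = "CD2 & !CD3",
    myeloid     = "CD16")
}

## Two-component Gaussian mixture on log intensities; returns the midpoint
## of the component means on the intensity scale, or NA when the fit looks
## unimodal (component gap under 4 RMS within-component SDs -- a single
## Gaussian split in two shows a gap of only ~2.7).
auto_threshold <- function(x) {
  lx <- log(pmax(x, .Machine$double.xmin))
  if (diff(range(lx)) < 1e-8) return(NA_real_)
  fit <- tryCatch(
    mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  mu <- sort(fit$parameters$mean)
  rms_sd <- sqrt(mean(fit$parameters$variance$sigmasq))
  if (!is.finite(rms_sd) || (mu[2] - mu[1]) < 4 * rms_sd) return(NA_real_)
  exp(mean(mu))
}

#' Gate marker intensities into positivity calls
#'
#' A cell is positive for a marker when its intensity is greater than or
#' equal to the threshold (boundary counts as positive). Thresholds are
#' either fixed numbers or "auto", which places the cutoff at the midpoint
#' (log scale) between the two intensity modes; if no bimodal structure is
#' found, the midpoint of the observed range is used with a warning.
#'
#' @param cells mIHC-flavor cell table.
#' @param gating Named list/vector of per-marker thresholds (numeric or
#'   "auto"). Markers absent from `gating` are not gated.
#' @return data.frame: `cell_id` plus one logical column per gated marker.
#'   Attribute `thresholds` records the cutoffs used.
#' @export
gate_cells <- function(cells, gating) {
  markers <- names(gating)
  absent <- setdiff(markers, colnames(cells))
  if (length(absent) > 0)
    stop("gating error: marker(s) missing from cell table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- data.frame(cell_id = cells$cell_id, stringsAsFactors = FALSE)
  used <- numeric(0)
  for (m in markers) {
    thr <- gating[[m]]
    if (identical(thr, "auto")) {
      thr <- auto_threshold(cells[[m]])
      if (is.na(thr)) {
        warning(sprintf("marker %s: no bimodal structure found; using midpoint of range", m))
        thr <- mean(range(cells[[m]]))
      }
    }
    if (!is.numeric(thr) || !is.finite(thr) || thr <= 0)
      stop(sprintf("gating error: threshold for %s must be positive and finite", m),
           call. = FALSE)
    out[[m]] <- cells[[m]] >= thr
    used[m] <- thr
  }
  attr(out, "thresholds") <- used
  out
}

#' Classify cells into (possibly overlapping) immune classes
#'
#' @param positivity Output of [gate_cells()].
#' @param rules Named character vector of boolean expressions over gated
#'   markers, as [default_class_rules()].
#' @return data.frame: `cell_id` plus one logical column per class. A cell
#'   may satisfy several classes; a cell satisfying none has all-FALSE.
#' @export
classify_cell_types <- function(positivity, rules = default_class_rules()) {
  marker_cols <- setdiff(colnames(positivity), "cell_id")
  out <- data.frame(cell_id = positivity$cell_id, stringsAsFactors = FALSE)
  for (cl in names(rules)) {
    expr <- parse(text = rules[[cl]])[[1]]
    vars <- all.vars(expr)
    unknown <- setdiff(vars, marker_cols)
    if (length(unknown) > 0)
      stop(sprintf("class rule '%s' references unknown marker(s): %s",
                   cl, paste(unknown, collapse = ", ")), call. = FALSE)
    out[[cl]] <- eval(expr, envir = positivity)
  }
  out
}

#' Combine cells, positivity and classes into one gated-cohort frame
#'
#' Convenience join used by the phenotype and interaction layers; class
#' columns are prefixed `class_` and positivity columns `pos_`.
#'
#' @param cells mIHC cell table.
#' @param positivity From [gate_cells()].
#' @param classes From [classify_cell_types()].
#' @return data.frame keyed by `cell_id`.
#' @export
gated_cohort <- function(cells, positivity, classes) {
  pos <- positivity; colnames(pos)[-1] <- paste0("pos_", colnames(pos)[-1])
  cls <- classes;    colnames(cls)[-1] <- paste0("class_", colnames(cls)[-1])
  out <- merge(cells[, intersect(c(CELL_BASE_COLS, "is_lymphocyte"), colnames(cells))],
               pos, by = "cell_id")
  out <- merge(out, cls, by = "cell_id")
  out[order(out$cell_id), , drop = FALSE]
}

#' Phenotype definition
#'
#' An immunophenotype is a cell class plus 0-2 positivity markers, with the
#' proportion taken either to all cells or to the parent class (e.g.,
#' cytotoxic T PD1+LAG3+ as a proportion of cytotoxic T cells).
#'
#' @param class Class name (must match a classification rule).
#' @param markers Character vector (possibly empty) of required-positive
#'   markers.
#' @param denominator "all_cells" or "parent_class".
#' @param name Optional display name.
#' @return List of class `phenotype_def`.
#' @export
phenotype_def <- function(class, markers = character(0),
                          denominator = c("all_cells", "parent_class"),
                          name = NULL) {
  denominator <- match.arg(denominator)
  name <- name %||% paste0(
    class,
    if (length(markers) > 0) paste0("/", paste0(markers, "+", collapse = "")) else ""
  )
  structure(list(class = class, markers = markers, denominator = denominator,
                 name = name), class = "phenotype_def")
}

## Rows of `gc` matching a phenotype numerator / denominator.
phenotype_numerator <- function(gc, ph) {
  sel <- gc[[paste0("class_", ph$class)]]
  for (m in ph$markers) sel <- sel & gc[[paste0("pos_", m)]]
  sel
}

#' Compute one phenotype proportion
#'
#' @param gc Gated cohort frame ([gated_cohort()]), already subset to the
#'   cells of interest (e.g., one patient-region).
#' @param ph A [phenotype_def()].
#' @param min_cells Minimum denominator size; below it the proportion is
#'   NA (unstable ratio guard, default 10).
#' @return Proportion in [0,1], or NA.
#' @export
phenotype_proportion <- function(gc, ph, min_cells = 10) {
  num <- phenotype_numerator(gc, ph)
  denom <- if (ph$denominator == "all_cells") rep(TRUE, nrow(gc))
           else gc[[paste0("class_", ph$class)]]
  n_den <- sum(denom)
  if (n_den < min_cells) return(NA_real_)
  if (ph$denominator == "all_cells") sum(num) / n_den
  else sum(num & denom) / n_den
}

#' Default phenotype panel
#'
#' Class proportions of all cells plus checkpoint/memory/cytolytic marker
#' proportions within each T-cell class and NK cells.
#'
#' @param markers Phenotype markers to cross with the classes.
#' @return List of [phenotype_def()]s.
#' @export
default_phenotype_panel <- function(markers = c("PD1", "LAG3", "TIM3", "CD45RO", "GrB")) {
  defs <- list(
    phenotype_def("T"), phenotype_def("helper_T"), phenotype_def("cytotoxic_T"),
    phenotype_def("NK"), phenotype_def("myeloid")
  )
  for (cl in c("T", "helper_T", "cytotoxic_T", "NK"))
    for (m in markers)
      defs[[length(defs) + 1]] <- phenotype_def(cl, m, "parent_class")
  defs
}

#' Build the patient-by-phenotype proportion matrix
#'
#' One row per patient-region, one column per phenotype. The
#' contexture-level summary (per-region median across patients) is attached
#' as attribute `contexture`.
#'
#' @param gc Gated cohort frame.
#' @param panel List of [phenotype_def()]s.
#' @param min_cells Passed to [phenotype_proportion()].
#' @return data.frame with `patient_id`, `region` and one numeric column
#'   per phenotype (NA when the denominator rule fails).
#' @export
build_phenotype_matrix <- function(gc, panel = default_phenotype_panel(),
                                   min_cells = 10) {
  keys <- unique(gc[, c("patient_id", "region")])
  keys <- keys[order(keys$patient_id, keys$region), , drop = FALSE]
  groups <- split(gc, paste(gc$patient_id, gc$region, sep = "\r"))
  out <- keys
  for (ph in panel) {
    vals <- vapply(paste(keys$patient_id, keys$region, sep = "\r"), function(k)
      phenotype_proportion(groups[[k]], ph, min_cells = min_cells), numeric(1))
    out[[ph$name]] <- unname(vals)
  }
  rownames(out) <- NULL
  pheno_cols <- vapply(panel, function(p) p$name, character(1))
  ctx <- aggregate(out[pheno_cols], by = list(region = out$region),
                   FUN = median, na.rm = TRUE)
  attr(out, "contexture") <- ctx
  attr(out, "phenotypes") <- pheno_cols
  out
}

#' Median-centre and max-scale a matrix for heatmap display
#'
#' Column-wise (per feature): subtract the median across rows, then divide
#' by the maximum absolute centred value. A constant column maps to zeros.
#' After normalization every column satisfies max|value| <= 1.
#'
#' @param m Numeric matrix or the data.frame from
#'   [build_phenotype_matrix()] (id columns are passed through).
#' @return Object of the same shape, normalized.
#' @export
normalize_for_heatmap <- function(m) {
  if (is.data.frame(m)) {
    num <- vapply(m, is.numeric, logical(1))
    m[num] <- lapply(m[num], function(x) normalize_column(x))
    return(m)
  }
  apply(m, 2, normalize_column)
}

normalize_column <- function(x) {
  if (all(!is.finite(x))) return(x)
  ctr <- x - median(x, na.rm = TRUE)
  mx <- max(abs(ctr), na.rm = TRUE)
  if (mx == 0) return(ctr)
  ctr / mx
}

#' Hierarchical clustering of immune profiles
#'
#' Rows (and optionally columns) are clustered with Ward.D2 linkage on
#' Spearman correlation distance (1 - rho), the convention used for immune
#' contexture heatmaps. Rows with zero variance (correlation undefined) are
#' excluded from clustering and reported separately. Distance
#' "euclidean_cor" instead embeds each row by its vector of Spearman
#' correlations to all rows and takes Euclidean distances between those
#' vectors.
#'
#' @param m Numeric matrix (rows = profiles).
#' @param distance "spearman" (1 - rho) or "euclidean_cor".
#' @return List with `hclust` (stats::hclust object), `order` (row indices
#'   in leaf order, unclusterable rows appended last) and `unclustered`.
#' @export
cluster_profiles <- function(m, distance = c("spearman", "euclidean_cor")) {
  distance <- match.arg(distance)
  m <- as.matrix(m)
  variable <- apply(m, 1, function(r) {
    r <- r[is.finite(r)]; length(r) >= 2 && diff(range(r)) > 0
  })
  if (sum(variable) < 3)
    stop("cluster_profiles needs at least 3 clusterable (non-constant) rows",
         call. = FALSE)
  mm <- m[variable, , drop = FALSE]
  rho <- suppressWarnings(cor(t(mm), method = "spearman",
                              use = "pairwise.complete.obs"))
  rho[!is.finite(rho)] <- 0
  d <- if (distance == "spearman") as.dist(1 - rho) else dist(rho)
  hc <- hclust(d, method = "ward.D2")
  list(hclust = hc,
       order = unname(c(which(variable)[hc$order], which(!variable))),
       unclustered = unname(which(!variable)))
}

#' Spearman correlation of phenotypes between IT and PT regions
#'
#' For each phenotype, correlates the IT and PT proportions across patients
#' having both regions; p-values are BH-adjusted across phenotypes.
#'
#' @param mat Output of [build_phenotype_matrix()].
#' @param min_pairs Minimum complete patient pairs (default 5).
#' @param groups Optional named list mapping group names to phenotype
#'   names; group median correlations are attached as attribute
#'   `group_medians`.
#' @return data.frame with `phenotype`, `n`, `rho`, `p_value`, `q_value`.
#' @export
correlate_it_pt <- function(mat, min_pairs = 5, groups = NULL) {
  phenos <- attr(mat, "phenotypes") %||%
    setdiff(colnames(mat), c("patient_id", "region"))
  it <- mat[mat$region == "IT", c("patient_id", phenos)]
  pt <- mat[mat$region == "PT", c("patient_id", phenos)]
  merged <- merge(it, pt, by = "patient_id", suffixes = c(".IT", ".PT"))
  rows <- lapply(phenos, function(ph) {
    x <- merged[[paste0(ph, ".IT")]]; y <- merged[[paste0(ph, ".PT")]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_pairs)
      return(data.frame(phenotype = ph, n = sum(ok), rho = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(phenotype = ph, n = sum(ok), rho = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- adjust_bh(out$p_value[ok])
  if (!is.null(groups)) {
    gm <- vapply(groups, function(g)
      median(out$rho[out$phenotype %in% g], na.rm = TRUE), numeric(1))
    attr(out, "group_medians") <- gm
  }
  out
}
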