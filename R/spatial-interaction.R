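## Cell-cell spatial interaction analysis ----------------------------------
##
## Two cells interact when their Euclidean distance is at most 100 pixels
## (22 um at 0.22 um/pixel). For cell types a and b with m and n cells in a
## sample of c cells, the interaction frequency i_ab counts interacting
## (a, b) pairs and the normalized interaction index is
##     I_ab = i_ab * c / sqrt(m * n),
## i.e., the pair count divided by the geometric-mean pair proportion
## sqrt(m * n) / c, which removes the dependence on cell-type abundance.

#' Interaction analysis configuration
#'
#' @param threshold_px Interaction radius in pixels (inclusive).
#' @param pixel_size_um Physical pixel size; used only for reporting
#'   (`threshold_um = threshold_px * pixel_size_um`).
#' @param types Cell classes whose pairwise interactions are computed.
#' @param normalization "geometric" for I_ab = i_ab c / sqrt(mn) (default)
#'   or "sum" for i_ab c / sqrt(m + n).
#' @return List of class `interaction_config`.
#' @export
interaction_config <- function(threshold_px = 100, pixel_size_um = 0.22,
                               types = c("T", "helper_T", "cytotoxic_T", "NK", "myeloid"),
                               normalization = c("geometric", "sum")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(threshold_px) || threshold_px <= 0)
    stop("interaction threshold must be positive", call. = FALSE)
  structure(list(threshold_px = threshold_px, pixel_size_um = pixel_size_um,
                 threshold_um = threshold_px * pixel_size_um,
                 types = types, normalization = normalization),
            class = "interaction_config")
}

#' Euclidean distance between two cells
#'
#' @param cell_a,cell_b Numeric `c(x, y)` coordinates in pixels.
#' @return Distance in pixels.
#' @export
pair_distance <- function(cell_a, cell_b) {
  if (!all(is.finite(cell_a[1:2])) || !all(is.finite(cell_b[1:2])))
    stop("pair_distance requires finite coordinates", call. = FALSE)
  sqrt((cell_a[1] - cell_b[1])^2 + (cell_a[2] - cell_b[2])^2)
}

#' Binary interaction call for a distance
#'
#' @param distance Distance(s) in pixels, nonnegative.
#' @param threshold Interaction radius (inclusive; a pair at exactly the
#'   threshold interacts).
#' @return Integer 0/1 vector.
#' @export
is_interacting <- function(distance, threshold = 100) {
  stopifnot(all(distance >= 0))
  as.integer(distance <= threshold)
}

#' Interaction frequency i_ab between two cell sets
#'
#' Counts pairs (j in a, k in b) within the threshold. Pairs formed by the
#' same physical cell appearing in both sets (shared `cell_id`, as happens
#' with overlapping classes) are excluded. When the two sets are identical,
#' unordered distinct pairs j < k are counted. Counting uses a grid
#' partition with bin width equal to the threshold and agrees exactly with
#' the brute-force double loop.
#'
#' @param cells_a,cells_b data.frames with `cell_id`, `x_px`, `y_px` (and
#'   optionally `region`, which must be homogeneous across both sets).
#' @param config An [interaction_config()].
#' @return Integer pair count.
#' @export
interaction_frequency <- function(cells_a, cells_b, config = interaction_config()) {
  regions <- unique(c(cells_a$region, cells_b$region))
  if (length(regions) > 1)
    stop("interaction_frequency: cells span multiple regions; interactions are never computed across region boundaries",
         call. = FALSE)
  m <- nrow(cells_a); n <- nrow(cells_b)
  if (m == 0 || n == 0) return(0L)
  thr <- config$threshold_px
  counts <- radius_neighbour_counts(cells_a$x_px, cells_a$y_px,
                                    cells_b$x_px, cells_b$y_px, thr)
  total <- sum(counts)
  same_set <- m == n && setequal(cells_a$cell_id, cells_b$cell_id)
  shared <- length(intersect(cells_a$cell_id, cells_b$cell_id))
  if (same_set) as.integer((total - m) / 2) else as.integer(total - shared)
}

#' Normalized interaction index I_ab
#'
#' @param i_ab Interacting-pair count.
#' @param m,n Counts of type-a and type-b cells.
#' @param c_total Total cell count in the sample.
#' @param normalization "geometric" (I = i c / sqrt(mn)) or "sum"
#'   (I = i c / sqrt(m + n)).
#' @return Nonnegative index, or NA when m or n is zero.
#' @export
interaction_index <- function(i_ab, m, n, c_total,
                              normalization = c("geometric", "sum")) {
  normalization <- match.arg(normalization)
  if (m <= 0 || n <= 0) return(NA_real_)
  stopifnot(c_total >= max(m, n), i_ab >= 0)
  denom <- if (normalization == "geometric") sqrt(m * n) else sqrt(m + n)
  i_ab * c_total / denom
}

#' All pairwise interaction records for a classified cohort
#'
#' Computes, for every patient, region and unordered pair of configured
#' types (including self-pairs), the interaction frequency, the type
#' counts, the total cell count and the normalized index. Cells never pair
#' across regions or patients. When a patient contributes several cores,
#' `i_ab`, `m`, `n` and `c` are summed across cores before the index is
#' computed (pairs never span cores either).
#'
#' @param gc Gated cohort frame ([gated_cohort()]).
#' @param config An [interaction_config()].
#' @return data.frame with `patient_id`, `region`, `type_a`, `type_b`,
#'   `i_ab`, `m`, `n`, `c_total`, `index`.
#' @export
interaction_matrix <- function(gc, config = interaction_config()) {
  types <- config$types
  cls_cols <- paste0("class_", types)
  missing_cls <- setdiff(cls_cols, colnames(gc))
  if (length(missing_cls) > 0)
    stop("interaction_matrix: cohort lacks class column(s) ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  pairs <- which(upper.tri(matrix(0, length(types), length(types)), diag = TRUE),
                 arr.ind = TRUE)
  groups <- split(gc, list(gc$patient_id, gc$region, gc$core_id), drop = TRUE)
  acc <- list()
  for (grp in groups) {
    pid <- grp$patient_id[1]; reg <- grp$region[1]
    for (r in seq_len(nrow(pairs))) {
      ta <- types[pairs[r, 1]]; tb <- types[pairs[r, 2]]
      ca <- grp[grp[[paste0("class_", ta)]], c("cell_id", "x_px", "y_px", "region")]
      cb <- grp[grp[[paste0("class_", tb)]], c("cell_id", "x_px", "y_px", "region")]
      key <- paste(pid, reg, ta, tb, sep = "\r")
      prev <- acc[[key]] %||% list(i = 0L, m = 0L, n = 0L, c = 0L)
      acc[[key]] <- list(
        i = prev$i + interaction_frequency(ca, cb, config),
        m = prev$m + nrow(ca), n = prev$n + nrow(cb),
        c = prev$c + nrow(grp)
      )
    }
  }
  keys <- strsplit(names(acc), "\r", fixed = TRUE)
  out <- data.frame(
    patient_id = vapply(keys, `[`, "", 1), region = vapply(keys, `[`, "", 2),
    type_a = vapply(keys, `[`, "", 3), type_b = vapply(keys, `[`, "", 4),
    i_ab = vapply(acc, function(x) as.integer(x$i), integer(1)),
    m = vapply(acc, function(x) as.integer(x$m), integer(1)),
    n = vapply(acc, function(x) as.integer(x$n), integer(1)),
    c_total = vapply(acc, function(x) as.integer(x$c), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$index <- mapply(interaction_index, out$i_ab, out$m, out$n, out$c_total,
                      MoreArgs = list(normalization = config$normalization))
  out[order(out$patient_id, out$region, out$type_a, out$type_b), , drop = FALSE]
}

#' Flag focal cells interacting with a partner type
#'
#' A focal cell is flagged when at least one *distinct* cell of the partner
#' type (self excluded by `cell_id`) lies within the threshold in the same
#' patient, region and core.
#'
#' @param gc Gated cohort frame.
#' @param focal_type,partner_type Class names.
#' @param config An [interaction_config()].
#' @return data.frame with `cell_id` (focal cells) and logical
#'   `interacting`.
#' @export
flag_interacting_cells <- function(gc, focal_type, partner_type,
                                   config = interaction_config()) {
  fcol <- paste0("class_", focal_type); pcol <- paste0("class_", partner_type)
  stopifnot(fcol %in% colnames(gc), pcol %in% colnames(gc))
  groups <- split(gc, list(gc$patient_id, gc$region, gc$core_id), drop = TRUE)
  parts <- lapply(groups, function(grp) {
    foc <- grp[grp[[fcol]], , drop = FALSE]
    par <- grp[grp[[pcol]], , drop = FALSE]
    if (nrow(foc) == 0) return(NULL)
    if (nrow(par) == 0)
      return(data.frame(cell_id = foc$cell_id, interacting = FALSE,
                        stringsAsFactors = FALSE))
    cnt <- radius_neighbour_counts(foc$x_px, foc$y_px, par$x_px, par$y_px,
                                   config$threshold_px)
    cnt <- cnt - as.integer(foc$cell_id %in% par$cell_id)  # self is always within 0 px
    data.frame(cell_id = foc$cell_id, interacting = cnt > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), interacting = logical(0))
  rownames(out) <- NULL
  out
}

#' Interaction-conditioned phenotype fold change
#'
#' For a focal/partner type pair and a set of phenotype markers, compares
#' marker-positive proportions of interacting vs. non-interacting focal
#' cells. Per patient and region, both groups must meet `min_cells`;
#' proportions are then summarised across patients and the fold change is
#' FC = log10(median p_interacting / median p_non-interacting). The
#' p-value is a two-sided paired Wilcoxon signed-rank test across patients;
#' q-values are BH-adjusted across the markers of the call.
#'
#' @param gc Gated cohort frame.
#' @param focal_type,partner_type Class names.
#' @param markers Phenotype markers (gated columns).
#' @param config An [interaction_config()].
#' @param min_cells Minimum focal cells per group per patient (default 10).
#' @return data.frame per region x marker: `n_patients`, `median_int`,
#'   `median_non`, `log10_fc`, `p_value`, `q_value`.
#' @export
interaction_phenotype_fc <- function(gc, focal_type, partner_type, markers,
                                     config = interaction_config(),
                                     min_cells = 10) {
  flags <- flag_interacting_cells(gc, focal_type, partner_type, config)
  foc <- merge(gc[gc[[paste0("class_", focal_type)]], , drop = FALSE],
               flags, by = "cell_id")
  rows <- list()
  for (reg in unique(foc$region)) {
    fr <- foc[foc$region == reg, , drop = FALSE]
    for (m in markers) {
      pcol <- paste0("pos_", m)
      if (!pcol %in% colnames(fr))
        stop("interaction_phenotype_fc: marker not gated: ", m, call. = FALSE)
      per_pat <- lapply(split(fr, fr$patient_id), function(pp) {
        n_int <- sum(pp$interacting); n_non <- sum(!pp$interacting)
        if (n_int < min_cells || n_non < min_cells) return(NULL)
        c(p_int = mean(pp[[pcol]][pp$interacting]),
          p_non = mean(pp[[pcol]][!pp$interacting]))
      })
      per_pat <- do.call(rbind, Filter(Negate(is.null), per_pat))
      if (is.null(per_pat) || nrow(per_pat) < 3) {
        rows[[paste(reg, m)]] <- data.frame(
          region = reg, marker = m, n_patients = if (is.null(per_pat)) 0L else nrow(per_pat),
          median_int = NA_real_, median_non = NA_real_, log10_fc = NA_real_,
          p_value = NA_real_, stringsAsFactors = FALSE)
        next
      }
      med_i <- median(per_pat[, "p_int"]); med_n <- median(per_pat[, "p_non"])
      fc <- if (med_i > 0 && med_n > 0) log10(med_i / med_n) else NA_real_
      pv <- tryCatch(
        suppressWarnings(wilcox.test(per_pat[, "p_int"], per_pat[, "p_non"],
                                     paired = TRUE)$p.value),
        error = function(e) NA_real_)
      rows[[paste(reg, m)]] <- data.frame(
        region = reg, marker = m, n_patients = nrow(per_pat),
        median_int = med_i, median_non = med_n, log10_fc = fc,
        p_value = pv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- adjust_bh(out$p_value[ok])
  out
}

#' Digital staining: plot cell positions coloured by phenotype
#'
#' Scatter of cell coordinates faceted by region, highlighting cells that
#' match a phenotype (class + optional positive markers), emulating a
#' digitally reproduced mIHC staining.
#'
#' @param gc Gated cohort frame (typically one patient).
#' @param ph A [phenotype_def()].
#' @param out_path Output figure path (png/pdf/svg by extension).
#' @return `out_path` invisibly, with attribute `n_points` (cells drawn)
#'   and `n_positive` (phenotype-positive cells).
#' @export
digital_stain <- function(gc, ph, out_path) {
  cls_col <- paste0("class_", ph$class)
  if (!cls_col %in% colnames(gc))
    stop("digital_stain: unknown phenotype class ", ph$class, call. = FALSE)
  gc$phenotype_positive <- phenotype_numerator(gc, ph)
  p <- ggplot2::ggplot(gc, ggplot2::aes(x = .data$x_px, y = .data$y_px)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phenotype_positive),
                        size = 0.4, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey80", `TRUE` = "red3"),
                                 name = ph$name, drop = FALSE) +
    ggplot2::facet_wrap(~region, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  ggplot2::ggsave(out_path, p, width = 7, height = 4, dpi = 150)
  out <- out_path
  attr(out, "n_points") <- nrow(gc)
  attr(out, "n_positive") <- sum(gc$phenotype_positive)
  invisible(out)
}
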