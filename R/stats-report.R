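## Statistical utilities and the clinical/survival layer -------------------

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] after input validation).
#'
#' @param p Vector of p-values in [0,1].
#' @return Adjusted q-values, monotone in rank and bounded by 1.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("adjust_bh: p-values must lie in [0,1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Compare a continuous feature between groups
#'
#' Two groups are compared with the unpaired two-sided Wilcoxon rank-sum
#' (Mann-Whitney) test, three or more with the Kruskal-Wallis test. For two
#' groups the fold change of medians, log10(median_1 / median_2), is
#' reported (NA when either median is zero or negative).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return One-row data.frame: `n_groups`, `statistic`, `p_value`,
#'   `log10_fc` (group order: first factor level vs. the rest).
#' @export
compare_groups <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2) stop("compare_groups needs at least 2 non-empty groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("compare_groups: a group has fewer than 2 observations; p set to NA")
    return(data.frame(n_groups = k, statistic = NA_real_, p_value = NA_real_,
                      log10_fc = NA_real_))
  }
  if (k == 2) {
    g1 <- values[groups == levels(groups)[1]]
    g2 <- values[groups == levels(groups)[2]]
    ht <- suppressWarnings(wilcox.test(g1, g2, alternative = "two.sided"))
    m1 <- median(g1); m2 <- median(g2)
    fc <- if (m1 > 0 && m2 > 0) log10(m1 / m2) else NA_real_
    data.frame(n_groups = 2L, statistic = unname(ht$statistic),
               p_value = ht$p.value, log10_fc = fc)
  } else {
    ht <- kruskal.test(values, groups)
    data.frame(n_groups = k, statistic = unname(ht$statistic),
               p_value = ht$p.value, log10_fc = NA_real_)
  }
}

#' Median dichotomization of a clinical variable
#'
#' "high" means strictly above the median; values equal to the median go to
#' "low" (documented tie convention, configurable).
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param ties "low" (default) or "high": side receiving values equal to
#'   the median.
#' @return Factor with levels `low`, `high` (NA preserved).
#' @export
dichotomize_by_median <- function(values, ties = c("low", "high")) {
  ties <- match.arg(ties)
  fin <- values[is.finite(values)]
  if (length(fin) < 2) stop("dichotomize_by_median needs >= 2 finite values", call. = FALSE)
  if (diff(range(fin)) == 0)
    stop("dichotomize_by_median: all values identical (degenerate split)", call. = FALSE)
  med <- median(fin)
  high <- if (ties == "low") values > med else values >= med
  factor(ifelse(high, "high", "low"), levels = c("low", "high"))
}

#' Univariate Cox survival screen for one feature
#'
#' Fits a univariate proportional-hazards model of overall survival on the
#' feature (median-dichotomized by default) and reports the hazard ratio
#' with Wald 95% CI and the log-rank (score) p-value. Kaplan-Meier
#' coordinates for plotting are attached as attribute `km` when the feature
#' is dichotomized.
#'
#' @param feature Numeric vector aligned with `clinical` rows, or the name
#'   of a `clinical` column.
#' @param clinical Clinical table with `os_time`, `os_event`.
#' @param dichotomize Median-split the feature first (default TRUE).
#' @return One-row data.frame: `hr`, `ci_low`, `ci_high`, `logrank_p`,
#'   `n`, `events`, `converged`.
#' @export
cox_survival <- function(feature, clinical, dichotomize = TRUE) {
  if (is.character(feature) && length(feature) == 1)
    feature <- clinical[[feature]]
  stopifnot(length(feature) == nrow(clinical))
  ok <- is.finite(clinical$os_time) & !is.na(clinical$os_event) & !is.na(feature)
  time <- clinical$os_time[ok]; event <- clinical$os_event[ok]; x <- feature[ok]
  if (length(x) < 10) stop("cox_survival needs at least 10 patients", call. = FALSE)
  if (sum(event) < 3) stop("cox_survival needs at least 3 events", call. = FALSE)
  if (dichotomize && !is.factor(x)) x <- dichotomize_by_median(x)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x),
    warning = function(w) structure(
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ x)),
      converged = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    return(data.frame(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      logrank_p = NA_real_, n = length(x),
                      events = sum(event), converged = FALSE))
  converged <- attr(fit, "converged") %||% TRUE
  s <- summary(fit)
  out <- data.frame(
    hr = unname(s$conf.int[1, "exp(coef)"]),
    ci_low = unname(s$conf.int[1, "lower .95"]),
    ci_high = unname(s$conf.int[1, "upper .95"]),
    logrank_p = unname(s$sctest["pvalue"]),
    n = length(x), events = sum(event), converged = converged
  )
  if (is.factor(x)) {
    km <- survival::survfit(survival::Surv(time, event) ~ x)
    attr(out, "km") <- data.frame(
      time = km$time, surv = km$surv, n_risk = km$n.risk,
      stratum = rep(names(km$strata), km$strata)
    )
  }
  out
}

#' Fold-change comparison panel across a grouping
#'
#' For a topography grouping (three classes), each class is compared
#' one-vs-rest per feature; for a two-class clinical dichotomy, a single
#' two-group comparison per feature is made. P-values are BH-adjusted
#' within the panel, and only features reaching `p_keep` in any comparison
#' are retained in the display table (the full table is attached as
#' attribute `all`).
#'
#' @param mat data.frame with `patient_id` (or patient rows) and numeric
#'   feature columns.
#' @param grouping Vector of class labels aligned with rows of `mat`.
#' @param features Feature columns to test; default all numeric columns.
#' @param p_keep Display threshold on the unadjusted p (default 0.05).
#' @param min_class Minimum patients per class (smaller classes are
#'   skipped with a warning; default 3).
#' @return data.frame with `feature`, `class`, `log10_fc`, `p_value`,
#'   `q_value`, filtered to the display rule.
#' @export
group_fc_panel <- function(mat, grouping, features = NULL, p_keep = 0.05,
                           min_class = 3) {
  grouping <- factor(grouping)
  grouping <- droplevels(grouping)
  if (nlevels(grouping) < 2)
    stop("group_fc_panel needs a grouping with at least 2 classes", call. = FALSE)
  if (is.null(features))
    features <- colnames(mat)[vapply(mat, is.numeric, logical(1))]
  classes <- levels(grouping)
  sizes <- table(grouping)
  usable <- names(sizes)[sizes >= min_class]
  skipped <- setdiff(classes, usable)
  if (length(skipped) > 0)
    warning("group_fc_panel: class(es) skipped (fewer than ", min_class,
            " patients): ", paste(skipped, collapse = ", "))
  one_vs_rest <- nlevels(grouping) > 2
  targets <- if (one_vs_rest) usable else usable[1]
  rows <- list()
  for (cl in targets) {
    g <- factor(ifelse(grouping == cl, cl, "rest"), levels = c(cl, "rest"))
    for (f in features) {
      cmp <- tryCatch(suppressWarnings(compare_groups(mat[[f]], g)),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      rows[[paste(cl, f)]] <- data.frame(
        feature = f, class = cl, log10_fc = cmp$log10_fc,
        p_value = cmp$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- adjust_bh(out$p_value[ok])
  keep_features <- unique(out$feature[!is.na(out$p_value) & out$p_value < p_keep])
  display <- out[out$feature %in% keep_features, , drop = FALSE]
  attr(display, "all") <- out
  display
}
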