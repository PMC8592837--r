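## Immune topography classification ----------------------------------------
##
## Patients are classified into immune hot / cold / excluded topographies by
## a two-phase unsupervised procedure on lymphocyte proportions: phase 1
## clusters the intratumoral (IT) proportion, phase 2 clusters the
## peritumoral-minus-intratumoral difference among non-hot patients. Both
## phases use agglomerative hierarchical clustering (Euclidean distance,
## Ward.D2 linkage) cut into two groups.

#' Per-patient, per-region lymphocyte proportions
#'
#' @param cells H&E-flavor cell table (must contain `is_lymphocyte`).
#' @return data.frame with `patient_id`, `region`, `n_cells`,
#'   `n_lymphocytes`, `proportion`.
#' @export
region_lymphocyte_proportion <- function(cells) {
  if (!"is_lymphocyte" %in% colnames(cells))
    stop("region_lymphocyte_proportion needs an H&E-flavor table (is_lymphocyte column)",
         call. = FALSE)
  if (nrow(cells) == 0)
    return(data.frame(patient_id = character(0), region = character(0),
                      n_cells = integer(0), n_lymphocytes = integer(0),
                      proportion = numeric(0)))
  agg <- aggregate(
    cbind(n_cells = rep(1L, nrow(cells)),
          n_lymphocytes = as.integer(cells$is_lymphocyte)),
    by = list(patient_id = cells$patient_id, region = cells$region), FUN = sum
  )
  agg$proportion <- agg$n_lymphocytes / agg$n_cells
  agg[order(agg$patient_id, agg$region), , drop = FALSE]
}

#' Arrange proportions into topography-assignment input
#'
#' Pivots the long proportion table into one row per patient with `it_prop`,
#' `pt_prop` and `delta = pt_prop - it_prop`. Control-only patients are
#' dropped; patients missing either tumour region keep an NA.
#'
#' @param props Output of [region_lymphocyte_proportion()].
#' @return data.frame with `patient_id`, `it_prop`, `pt_prop`, `delta`.
#' @export
topography_input <- function(props) {
  it <- props[props$region == "IT", c("patient_id", "proportion")]
  pt <- props[props$region == "PT", c("patient_id", "proportion")]
  names(it)[2] <- "it_prop"; names(pt)[2] <- "pt_prop"
  out <- merge(it, pt, by = "patient_id", all = TRUE)
  out$delta <- out$pt_prop - out$it_prop
  out[order(out$patient_id), , drop = FALSE]
}

## Cut 1-D values into two Ward.D2 clusters; returns cluster index 1/2.
ward_cut2 <- function(x) {
  hc <- hclust(dist(x), method = "ward.D2")
  cutree(hc, k = 2)
}

#' Assign immune topographies by two-phase clustering
#'
#' Phase 1 clusters the IT lymphocyte proportion (Euclidean distance,
#' Ward.D2, two clusters); the higher-mean cluster is labelled hot.
#' Phase 2 repeats the clustering on `delta = pt_prop - it_prop` restricted
#' to non-hot patients; the higher-mean-delta cluster is labelled excluded,
#' the other cold. Ties in cluster means break toward cold. The result is
#' invariant to row permutation and to adding a constant to all `it_prop`
#' values (only relative structure matters); rescaling is not invariant.
#'
#' @param props data.frame with `patient_id`, `it_prop`, `pt_prop` (and
#'   optionally `delta`; recomputed if absent). Patients with a missing
#'   proportion are excluded with a warning.
#' @param on_degenerate What to do when all inputs in a phase are identical:
#'   "error" (default) or "all_cold".
#' @return The input rows (complete cases), with `delta` and a `label`
#'   factor (hot/cold/excluded) added.
#' @export
assign_topographies <- function(props, on_degenerate = c("error", "all_cold")) {
  on_degenerate <- match.arg(on_degenerate)
  props$delta <- props$pt_prop - props$it_prop
  ok <- is.finite(props$it_prop) & is.finite(props$pt_prop)
  if (any(!ok)) {
    warning(sprintf("%d patient(s) excluded from topography assignment (missing region proportion)",
                    sum(!ok)))
    props <- props[ok, , drop = FALSE]
  }
  n <- nrow(props)
  if (n < 4) stop("topography assignment needs at least 4 patients with both regions",
                  call. = FALSE)
  degenerate <- function(x) diff(range(x)) < .Machine$double.eps * 100
  label <- rep(NA_character_, n)

  if (degenerate(props$it_prop)) {
    if (on_degenerate == "error")
      stop("degenerate input: all IT proportions identical; no cluster structure",
           call. = FALSE)
    label[] <- "cold"
  } else {
    cl1 <- ward_cut2(props$it_prop)
    means <- tapply(props$it_prop, cl1, mean)
    hot_cl <- if (means[["1"]] > means[["2"]]) 1L else 2L  # tie -> cluster 2 stays non-hot
    label[cl1 == hot_cl] <- "hot"
    rest <- which(cl1 != hot_cl)
    if (length(rest) < 2)
      stop("fewer non-hot patients than clusters in phase 2", call. = FALSE)
    d <- props$delta[rest]
    if (degenerate(d)) {
      if (on_degenerate == "error")
        stop("degenerate input: all non-hot delta values identical; no cluster structure",
             call. = FALSE)
      label[rest] <- "cold"
    } else {
      cl2 <- ward_cut2(d)
      dmeans <- tapply(d, cl2, mean)
      if (abs(dmeans[["1"]] - dmeans[["2"]]) < .Machine$double.eps * 100) {
        label[rest] <- "cold"   # tie broken toward the conservative class
      } else {
        excl_cl <- if (dmeans[["1"]] > dmeans[["2"]]) 1L else 2L
        label[rest] <- ifelse(cl2 == excl_cl, "excluded", "cold")
      }
    }
  }
  props$label <- factor(label, levels = c("hot", "cold", "excluded"))

  ## Post-condition: labelled cluster means are ordered as documented.
  if (any(props$label == "hot") && any(props$label != "hot"))
    stopifnot(mean(props$it_prop[props$label == "hot"]) >=
              mean(props$it_prop[props$label != "hot"]))
  if (any(props$label == "excluded") && any(props$label == "cold"))
    stopifnot(mean(props$delta[props$label == "excluded"]) >=
              mean(props$delta[props$label == "cold"]))
  props
}

#' Summarise topography class counts
#'
#' @param labels Factor or character vector of topography labels (or the
#'   data.frame returned by [assign_topographies()]).
#' @return data.frame with `label`, `n`, `percent` (one decimal);
#'   counts sum to the number of patients.
#' @export
topography_summary <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  tab <- table(labels)
  data.frame(label = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 1),
             stringsAsFactors = FALSE)
}

#' Two-by-two association test with chi-square/Fisher dispatch
#'
#' Applies a chi-square test with Yates continuity correction when every
#' observed cell count exceeds 5, and the two-sided Fisher exact test
#' otherwise. The dispatch can be overridden.
#'
#' @param tab 2x2 matrix of nonnegative integer counts, rows = group
#'   membership, columns = condition (e.g., mutated / wild-type).
#' @param test "auto" (dispatch rule), "chisq" or "fisher".
#' @return List with `p_value`, `odds_ratio` (sample OR ad/bc), `test_used`
#'   and `statistic` (Yates chi-square, when applicable).
#' @export
association_test_2x2 <- function(tab, test = c("auto", "chisq", "fisher")) {
  test <- match.arg(test)
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (test == "auto") test <- if (all(tab > 5)) "chisq" else "fisher"
  if (test == "chisq") {
    res <- suppressWarnings(chisq.test(tab, correct = TRUE))
    p <- res$p.value; stat <- unname(res$statistic)
  } else {
    res <- fisher.test(tab, alternative = "two.sided")
    p <- res$p.value; stat <- NA_real_
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = p, odds_ratio = or, test_used = test, statistic = stat)
}

#' Associate mutations with an immune topography class
#'
#' For each gene mutated in at least `min_prevalence` of labelled patients,
#' builds the 2x2 table (target class vs. rest) x (mutated vs. wild-type)
#' over patients with non-missing calls, tests it with the
#' chi-square/Fisher dispatch of [association_test_2x2()] and adjusts
#' p-values with Benjamini-Hochberg across genes.
#'
#' @param topo Labelled table from [assign_topographies()].
#' @param mutations Mutation table (patient_id + binary gene columns).
#' @param target_class Topography class tested against the pooled rest.
#' @param min_prevalence Minimum mutated fraction for a gene to be tested.
#' @param test_override NULL for the dispatch rule, or "chisq"/"fisher".
#' @return data.frame, one row per tested gene: counts
#'   (`mut_in`, `wt_in`, `mut_out`, `wt_out`), `odds_ratio`, `test_used`,
#'   `p_value`, `q_value`.
#' @export
mutation_topography_association <- function(topo, mutations, target_class,
                                            min_prevalence = 0.05,
                                            test_override = NULL) {
  stopifnot(target_class %in% c("hot", "cold", "excluded"))
  merged <- merge(topo[, c("patient_id", "label")], mutations, by = "patient_id")
  genes <- setdiff(colnames(mutations), "patient_id")
  in_class <- merged$label == target_class
  rows <- list()
  for (g in genes) {
    calls <- merged[[g]]
    ok <- !is.na(calls)
    if (mean(calls[ok]) < min_prevalence) next
    tab <- matrix(c(
      sum(calls[ok] == 1 & in_class[ok]),  sum(calls[ok] == 0 & in_class[ok]),
      sum(calls[ok] == 1 & !in_class[ok]), sum(calls[ok] == 0 & !in_class[ok])
    ), nrow = 2, byrow = TRUE,
    dimnames = list(c(target_class, "rest"), c("mut", "wt")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning(sprintf("gene %s skipped: empty 2x2 margin", g))
      next
    }
    res <- association_test_2x2(tab, test = test_override %||% "auto")
    rows[[g]] <- data.frame(
      gene = g, mut_in = tab[1, 1], wt_in = tab[1, 2],
      mut_out = tab[2, 1], wt_out = tab[2, 2],
      odds_ratio = res$odds_ratio, test_used = res$test_used,
      p_value = res$p_value, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(0), mut_in = integer(0), wt_in = integer(0),
                      mut_out = integer(0), wt_out = integer(0),
                      odds_ratio = numeric(0), test_used = character(0),
                      p_value = numeric(0), q_value = numeric(0)))
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out$q_value <- adjust_bh(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}
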