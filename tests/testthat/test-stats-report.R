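test_that("BH adjustment matches the step-up oracle and validates input", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.05, 6)), rep(0.05, 6))
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0,1\\]")
  set.seed(51)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("group comparison dispatches rank-sum vs Kruskal-Wallis with median fold change", {
  x <- c(1:10, 11:20)
  g <- rep(c("a", "b"), each = 10)
  res <- compare_groups(x, g)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value, ranksum_exact_oracle(1:10, 11:20), tolerance = 1e-10)

  same <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gt(same$p_value, 0.99)

  fc <- compare_groups(c(0.3, 0.3, 0.3, 0.03, 0.03, 0.03),
                       rep(c("a", "b"), each = 3))
  expect_equal(fc$log10_fc, 1)

  kw <- compare_groups(rnorm(30), rep(c("a", "b", "c"), 10))
  expect_equal(kw$n_groups, 3)
  expect_true(is.na(kw$log10_fc))
  expect_error(compare_groups(1:5, rep("a", 5)), "at least 2")
  expect_warning(compare_groups(1:5, c("a", rep("b", 4))), "fewer than 2")
})

test_that("exact rank-sum p-values match full enumeration for small groups", {
  set.seed(52)
  for (i in 1:20) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.5)
    res <- compare_groups(c(x, y), rep(c("a", "b"), c(nx, ny)))
    expect_equal(res$p_value, ranksum_exact_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("median dichotomization sends ties to the low class", {
  expect_equal(as.character(dichotomize_by_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomize_by_median(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  expect_equal(as.character(dichotomize_by_median(c(1, 2, 2, 3), ties = "high")),
               c("low", "high", "high", "high"))
  expect_error(dichotomize_by_median(rep(1, 5)), "identical")
  set.seed(53)
  v <- sample(1:20, 15, replace = TRUE)
  d <- dichotomize_by_median(v)
  n_ties <- sum(v == median(v))
  expect_lte(abs(sum(d == "high") - sum(d == "low")), n_ties + 1)
})

test_that("Cox screen recovers known hazard structure and enforces preconditions", {
  set.seed(54)
  covars <- data.frame(grp = rep(0:1, 250))
  s <- sample_survival(covars, list(baseline_rate = 1 / 1000,
                                    coefficients = c(grp = log(0.5)),
                                    censoring_rate = 0.2))
  clin <- data.frame(patient_id = seq_len(500), os_time = s$time, os_event = s$event)
  res <- cox_survival(covars$grp, clin, dichotomize = FALSE)
  expect_gt(res$hr, 0.4); expect_lt(res$hr, 0.62)
  expect_true(res$ci_low < res$hr && res$hr < res$ci_high)
  expect_lt(res$logrank_p, 0.001)

  # null: identical groups by construction
  set.seed(55)
  s0 <- sample_survival(data.frame(grp = rep(0:1, 500)),
                        list(baseline_rate = 1 / 1000, coefficients = c(grp = 0),
                             censoring_rate = 0.2))
  clin0 <- data.frame(patient_id = 1:1000, os_time = s0$time, os_event = s0$event)
  res0 <- cox_survival(rep(0:1, 500), clin0, dichotomize = FALSE)
  expect_gt(res0$hr, 0.8); expect_lt(res0$hr, 1.25)

  expect_error(cox_survival(rnorm(5), clin0[1:5, ]), "at least 10")
  no_events <- clin0[1:20, ]; no_events$os_event <- 0
  expect_error(cox_survival(rnorm(20), no_events), "at least 3 events")

  # dichotomized fit exports Kaplan-Meier coordinates
  resd <- cox_survival(rnorm(1000), clin0, dichotomize = TRUE)
  km <- attr(resd, "km")
  expect_true(!is.null(km) && all(c("time", "surv", "stratum") %in% colnames(km)))
})

test_that("group fold-change panel performs one-vs-rest comparisons with display filtering", {
  set.seed(56)
  n <- 36
  grouping <- rep(c("hot", "cold", "excluded"), each = n / 3)
  mat <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    up_in_hot = ifelse(grouping == "hot", rnorm(n, 2, 0.2), rnorm(n, 1, 0.2)),
    flat = rep(1, n))
  res <- group_fc_panel(mat, grouping)
  expect_true("up_in_hot" %in% res$feature)
  hot_row <- res[res$feature == "up_in_hot" & res$class == "hot", ]
  expect_gt(hot_row$log10_fc, 0)
  expect_lt(hot_row$p_value, 0.01)
  full <- attr(res, "all")
  expect_equal(nrow(full), 6)  # 3 classes x 2 features
  expect_false("flat" %in% res$feature)
  expect_error(group_fc_panel(mat, rep("one", n)), "at least 2")
  expect_warning(group_fc_panel(mat, c(rep("a", n - 2), "b", "b")), "skipped")
})

test_that("the end-to-end pipeline is deterministic and stage-error transparent", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- list(
    mode = "simulate",
    simulate = list(n_patients = 12,
                    cell_density = c(IT = 400, PT = 400, CTRL = 400), seed = 99),
    min_cells = 100,
    output_dir = dir1)
  run_pipeline(cfg)
  outputs <- c("topography.csv", "mutation_association.csv", "phenotype_matrix.csv",
               "phenotype_matrix_normalized.csv", "interactions.csv",
               "survival_excluded.csv", "provenance.json")
  expect_true(all(file.exists(file.path(dir1, outputs))))
  cfg$output_dir <- dir2
  run_pipeline(cfg)
  for (f in setdiff(outputs, "provenance.json"))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))

  bad <- list(mode = "files",
              inputs = list(cells = "nope.csv", clinical = "nope.csv",
                            mutations = "nope.csv"),
              output_dir = withr::local_tempdir())
  expect_error(run_pipeline(bad), "stage 'load'")
})
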