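test_that("regional lymphocyte proportions are plain ratios", {
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:120), patient_id = "P1", core_id = "P1_core1",
    region = rep(c("IT", "PT"), c(100, 20)),
    x_px = 0, y_px = 0,
    is_lymphocyte = c(rep(c(TRUE, FALSE), c(20, 80)), rep(TRUE, 20)),
    stringsAsFactors = FALSE)
  props <- region_lymphocyte_proportion(cells)
  expect_equal(props$proportion[props$region == "IT"], 0.20)
  expect_equal(props$proportion[props$region == "PT"], 1.0)

  coh <- small_cohort()
  props <- region_lymphocyte_proportion(coh$cells)
  direct <- tapply(coh$cells$is_lymphocyte,
                   paste(coh$cells$patient_id, coh$cells$region), mean)
  expect_equal(as.numeric(direct[paste(props$patient_id, props$region)]),
               props$proportion)
})

test_that("two-phase clustering labels well-separated 1-D data as expected", {
  it <- c(0.25, 0.28, 0.01, 0.02, 0.02, 0.03)
  delta <- c(0.05, 0.04, 0.20, 0.19, 0.00, 0.01)  # non-hot: P3..P6
  props <- data.frame(patient_id = sprintf("P%d", 1:6),
                      it_prop = it, pt_prop = it + delta)
  topo <- assign_topographies(props)
  expect_equal(as.character(topo$label),
               c("hot", "hot", "excluded", "excluded", "cold", "cold"))
  expect_equal(topo$delta, topo$pt_prop - topo$it_prop)
})

test_that("degenerate all-equal input errors by default with an all-cold fallback", {
  props <- data.frame(patient_id = sprintf("P%d", 1:5),
                      it_prop = rep(0.1, 5), pt_prop = rep(0.2, 5))
  expect_error(assign_topographies(props), "degenerate")
  fallback <- assign_topographies(props, on_degenerate = "all_cold")
  expect_true(all(fallback$label == "cold"))
  expect_error(assign_topographies(props[1:3, ]), "at least 4")
})

test_that("assignment is invariant to row permutation and constant shifts", {
  set.seed(21)
  props <- data.frame(
    patient_id = sprintf("P%02d", 1:30),
    it_prop = c(rnorm(8, 0.25, 0.01), rnorm(22, 0.03, 0.008)),
    pt_prop = c(rnorm(8, 0.20, 0.01), rnorm(15, 0.05, 0.008), rnorm(7, 0.22, 0.01)))
  base <- assign_topographies(props)
  perm <- sample(nrow(props))
  shuffled <- assign_topographies(props[perm, ])
  expect_equal(as.character(shuffled$label[order(shuffled$patient_id)]),
               as.character(base$label[order(base$patient_id)]))
  shifted <- props
  shifted$it_prop <- shifted$it_prop + 0.1
  shifted$pt_prop <- shifted$pt_prop + 0.1  # keeps delta unchanged too
  expect_equal(as.character(assign_topographies(shifted)$label),
               as.character(base$label))
  # phase-wise mean ordering holds
  expect_gte(mean(base$it_prop[base$label == "hot"]),
             mean(base$it_prop[base$label != "hot"]))
  expect_gte(mean(base$delta[base$label == "excluded"]),
             mean(base$delta[base$label == "cold"]))
})

test_that("Ward.D2 cut matches the optimal 1-D split on well-separated data", {
  set.seed(22)
  for (i in 1:20) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    x <- c(rnorm(n1, 0, 0.01), rnorm(n2, 0.5, 0.01))  # gap >> within-spread
    hc <- hclust(dist(x), method = "ward.D2")
    ward <- cutree(hc, k = 2)
    oracle <- best_1d_split(x)
    agree <- mean(ward == oracle)
    expect_true(agree %in% c(0, 1))  # identical up to label swap
  }
})

test_that("topography summary reproduces percentages from counts", {
  labels <- rep(c("hot", "cold", "excluded"), c(14, 38, 12))
  s <- topography_summary(labels)
  expect_equal(s$percent[s$label == "hot"], 21.9)
  expect_equal(s$percent[s$label == "cold"], 59.4)
  expect_equal(s$percent[s$label == "excluded"], 18.8)
  expect_equal(sum(s$n), 64)
  single <- topography_summary(rep("cold", 10))
  expect_equal(single$percent, 100)
})

test_that("2x2 dispatch rule and test results match independent oracles", {
  set.seed(23)
  for (i in 1:60) {
    tab <- matrix(rpois(4, sample(3:50, 1)), 2)
    res <- association_test_2x2(tab)
    expect_identical(res$test_used, if (all(tab > 5)) "chisq" else "fisher")
    expect_equal(res$p_value,
                 if (all(tab > 5)) yates_oracle(tab) else fisher_oracle(tab),
                 tolerance = 1e-10)
  }
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(association_test_2x2(even)$p_value, 1)
  forced <- association_test_2x2(matrix(c(25, 17, 17, 38), 2, byrow = TRUE),
                                 test = "fisher")
  expect_identical(forced$test_used, "fisher")
})

test_that("mutation association builds correct tables, dispatch and BH correction", {
  topo <- data.frame(patient_id = sprintf("P%02d", 1:40),
                     label = factor(rep(c("cold", "hot"), each = 20),
                                    levels = c("hot", "cold", "excluded")))
  set.seed(24)
  mutations <- data.frame(
    patient_id = topo$patient_id,
    GENEA = c(rep(1, 16), rep(0, 4), rep(1, 4), rep(0, 16)),  # cold-enriched
    GENEB = rbinom(40, 1, 0.5),
    RARE = c(1, rep(0, 39)))                                   # < 5% prevalence
  res <- mutation_topography_association(topo, mutations, "cold")
  expect_false("RARE" %in% res$gene)
  a <- res[res$gene == "GENEA", ]
  expect_equal(c(a$mut_in, a$wt_in, a$mut_out, a$wt_out), c(16, 4, 4, 16))
  expect_equal(a$odds_ratio, 16)
  expect_identical(a$test_used, "fisher")  # min cell = 4
  expect_equal(res$q_value, unname(bh_oracle(res$p_value)[order(res$p_value)]))
  # missing calls are dropped pairwise per gene
  mutations$GENEB[1:10] <- NA
  res2 <- mutation_topography_association(topo, mutations, "cold")
  b <- res2[res2$gene == "GENEB", ]
  expect_equal(b$mut_in + b$wt_in + b$mut_out + b$wt_out, 30)
})
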