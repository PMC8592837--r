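mk_pts <- function(x, y, id_prefix = "a", region = "IT") {
  data.frame(cell_id = sprintf("%s%03d", id_prefix, seq_along(x)),
             x_px = x, y_px = y, region = region, stringsAsFactors = FALSE)
}

test_that("pair distance and the inclusive interaction cutoff", {
  expect_equal(pair_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pair_distance(c(1, 1), c(1, 1)), 0)
  expect_equal(pair_distance(c(0, 0), c(60, 80)), 100)
  expect_error(pair_distance(c(NA, 0), c(1, 1)), "finite")
  expect_identical(is_interacting(c(0, 100, 100.001)), c(1L, 1L, 0L))
})

test_that("interaction frequency counts cross and self pairs correctly", {
  a <- mk_pts(0, 0, "a")
  b <- mk_pts(c(60, 200), c(80, 200), "b")
  expect_equal(interaction_frequency(a, b), 1L)

  line <- mk_pts(c(0, 90, 180), c(0, 0, 0), "s")
  expect_equal(interaction_frequency(line, line), 2L)

  # a cell shared between both type sets never pairs with itself
  shared <- mk_pts(c(0, 50), c(0, 0), "x")
  sub <- shared[1, ]
  expect_equal(interaction_frequency(shared, sub), 1L)

  mixed <- rbind(mk_pts(0, 0, "m", region = "IT"),
                 mk_pts(1, 1, "n", region = "PT"))
  expect_error(interaction_frequency(mixed, mixed), "region")
})

test_that("grid-accelerated counting equals the brute-force double loop", {
  set.seed(41)
  for (i in 1:25) {
    pts <- mk_pts(runif(200, 0, 700), runif(200, 0, 700), "p")
    a <- pts[1:20, ]; b <- pts[21:50, ]
    expect_identical(interaction_frequency(a, b), brute_pair_count(a, b))
    expect_identical(interaction_frequency(a, a), brute_pair_count(a, a))
    # overlapping sets (a subset of b), as with nested classes
    ab <- pts[1:40, ]
    expect_identical(interaction_frequency(a, ab), brute_pair_count(a, ab))
  }
})

test_that("interaction counts are symmetric, rigid-motion invariant and bounded", {
  set.seed(42)
  a <- mk_pts(runif(30, 0, 500), runif(30, 0, 500), "a")
  b <- mk_pts(runif(40, 0, 500), runif(40, 0, 500), "b")
  i_ab <- interaction_frequency(a, b)
  expect_identical(i_ab, interaction_frequency(b, a))
  expect_lte(i_ab, nrow(a) * nrow(b))
  expect_lte(interaction_frequency(a, a), nrow(a) * (nrow(a) - 1) / 2)

  move <- function(p, dx, dy, th) {
    xy <- cbind(p$x_px, p$y_px) %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    p$x_px <- xy[, 1] + dx; p$y_px <- xy[, 2] + dy; p
  }
  expect_identical(interaction_frequency(move(a, 123, -45, 0.7),
                                         move(b, 123, -45, 0.7)), i_ab)
  # scaling coordinates with a matching threshold leaves counts unchanged
  sc <- function(p, s) { p$x_px <- p$x_px * s; p$y_px <- p$y_px * s; p }
  expect_identical(
    interaction_frequency(sc(a, 3), sc(b, 3), interaction_config(threshold_px = 300)),
    i_ab)
  # monotone in the threshold
  thresholds <- c(10, 50, 100, 200, 400)
  counts <- vapply(thresholds, function(t)
    interaction_frequency(a, b, interaction_config(threshold_px = t)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the normalized index follows I = i c / sqrt(mn)", {
  expect_equal(interaction_index(4, 2, 3, 50), 4 * 50 / sqrt(6))
  expect_equal(interaction_index(4, 2, 3, 50), 81.6497, tolerance = 1e-4)
  expect_equal(interaction_index(0, 5, 7, 100), 0)
  expect_equal(interaction_index(4, 2, 3, 100), 2 * interaction_index(4, 2, 3, 50))
  expect_true(is.na(interaction_index(0, 0, 3, 50)))
  expect_equal(interaction_index(4, 2, 3, 50, normalization = "sum"),
               4 * 50 / sqrt(5))
})

test_that("the cohort interaction matrix respects patient, region and symmetry structure", {
  coh <- small_cohort()
  gc <- gate_and_classify(coh)
  cfg <- interaction_config()
  im <- interaction_matrix(gc, cfg)
  expect_true(all(im$i_ab >= 0))
  self <- im$type_a == im$type_b
  expect_true(all(im$i_ab[self] <= im$m[self] * (im$m[self] - 1) / 2))
  expect_true(all(im$i_ab[!self] <= im$m[!self] * im$n[!self]))
  expect_true(all(is.na(im$index) == (im$m == 0 | im$n == 0)))

  # spot-check one record against a direct recomputation
  rec <- im[im$m > 0 & im$n > 0 & im$type_a != im$type_b, ][1, ]
  grp <- gc[gc$patient_id == rec$patient_id & gc$region == rec$region, ]
  ca <- grp[grp[[paste0("class_", rec$type_a)]], c("cell_id", "x_px", "y_px", "region")]
  cb <- grp[grp[[paste0("class_", rec$type_b)]], c("cell_id", "x_px", "y_px", "region")]
  expect_identical(rec$i_ab, brute_pair_count(ca, cb))
  expect_identical(rec$i_ab, interaction_frequency(cb, ca, cfg))
  expect_equal(rec$index, rec$i_ab * rec$c_total / sqrt(rec$m * rec$n))

  # clustered cohorts have larger indexes than uniform ones at equal composition
  mk <- function(type) generate_cohort(cohort_config(
    n_patients = 8, cell_density = c(IT = 600, PT = 600, CTRL = 600),
    spatial_process = if (type == "clustered")
      list(type = "clustered", mean_offspring = 40, cluster_radius = 50,
           background_fraction = 0.3)
    else list(type = "uniform"),
    seed = 77))
  im_c <- interaction_matrix(gate_and_classify(mk("clustered")))
  im_u <- interaction_matrix(gate_and_classify(mk("uniform")))
  expect_gt(median(im_c$index, na.rm = TRUE), median(im_u$index, na.rm = TRUE))
})

test_that("interaction flags equal a brute-force neighbour scan and exclude self", {
  lone <- data.frame(
    cell_id = "z1", patient_id = "P1", core_id = "c1", region = "IT",
    x_px = 0, y_px = 0, class_T = TRUE, class_NK = FALSE)
  expect_false(flag_interacting_cells(lone, "T", "NK")$interacting)
  both <- lone; both$class_NK <- TRUE
  expect_false(flag_interacting_cells(both, "T", "NK")$interacting)

  coh <- small_cohort()
  gc <- gate_and_classify(coh)
  flags <- flag_interacting_cells(gc, "T", "NK")
  sub <- gc[gc$patient_id %in% c("P001", "P002"), ]
  for (pid in unique(sub$patient_id)) {
    for (reg in unique(sub$region[sub$patient_id == pid])) {
      grp <- sub[sub$patient_id == pid & sub$region == reg, ]
      foc <- grp[grp$class_T, ]; par <- grp[grp$class_NK, ]
      for (j in seq_len(nrow(foc))) {
        d <- sqrt((par$x_px - foc$x_px[j])^2 + (par$y_px - foc$y_px[j])^2)
        d <- d[par$cell_id != foc$cell_id[j]]
        expect_identical(flags$interacting[flags$cell_id == foc$cell_id[j]],
                         any(d <= 100))
      }
    }
  }
})

test_that("interaction-conditioned fold change has the documented null and scale", {
  set.seed(43)
  n <- 400
  gc <- data.frame(
    cell_id = sprintf("c%04d", 1:n),
    patient_id = rep(sprintf("P%02d", 1:8), each = 50),
    core_id = rep(sprintf("P%02d_c", 1:8), each = 50),
    region = "IT",
    x_px = runif(n, 0, 400), y_px = runif(n, 0, 400),
    class_T = rep(c(TRUE, FALSE), c(30, 20)),
    class_NK = rep(c(FALSE, TRUE), c(30, 20)),
    pos_M = rep(c(TRUE, FALSE), n / 2))
  res <- interaction_phenotype_fc(gc, "T", "NK", "M", min_cells = 2)
  # positivity is independent of interaction status: FC near 0, p not small
  expect_lt(abs(res$log10_fc), 0.35)
  expect_gt(res$p_value, 0.01)
  # a tenfold median ratio is one log10 unit by construction
  expect_equal(log10(0.2 / 0.02), 1)
  expect_error(interaction_phenotype_fc(gc, "T", "NK", "ZZ", min_cells = 2), "ZZ")
})

test_that("digital staining writes a non-empty figure with point-count metadata", {
  coh <- small_cohort()
  gc <- gate_and_classify(coh)
  one <- gc[gc$patient_id == "P001", ]
  path <- withr::local_tempfile(fileext = ".png")
  out <- digital_stain(one, phenotype_def("T", "TIM3"), path)
  expect_true(file.exists(path) && file.size(path) > 0)
  expect_equal(attr(out, "n_points"), nrow(one))
  expect_equal(attr(out, "n_positive"), sum(one$class_T & one$pos_TIM3))
  expect_error(digital_stain(one, phenotype_def("nosuch"), path), "unknown")
})
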