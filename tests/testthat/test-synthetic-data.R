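test_that("landscape generation is deterministic and spans the study climate", {
  a <- generate_landscape(10, 10, seed = 1)
  b <- generate_landscape(10, 10, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_landscape(10, 10, seed = 2)))
  # annual means span the stated regional ranges
  expect_lt(abs(min(a$cells$t_mean_ann) - (-4.7)), 0.5)
  expect_lt(abs(max(a$cells$t_mean_ann) - 6.7), 0.5)
  expect_lt(abs(min(a$cells$prec_ann) - 700), 60)
  expect_lt(abs(max(a$cells$prec_ann) - 1600), 60)
  expect_equal(nrow(a$monthly), 100 * 12)
  expect_error(generate_landscape(1, 10, seed = 1), ">= 2")
})

test_that("temperature decreases poleward and CMI varies longitudinally", {
  land <- generate_landscape(4, 25, seed = 7)
  clim <- landscape_climate(land)
  cells <- merge(land$cells, clim, by = "cell_id")
  expect_lt(cor(cells$iy, cells$tmax, method = "spearman"), 0)
  expect_gt(cor(cells$ix, cells$cmi_gs, method = "spearman"), 0)
  # moisture nearly orthogonal to temperature, as in the study region
  expect_lt(cor(cells$cmi_gs, cells$tmax)^2, 0.25)
  # zone boundary is a single latitude threshold
  boreal_rows <- unique(cells$iy[cells$zone == "boreal"])
  temperate_rows <- unique(cells$iy[cells$zone == "temperate"])
  expect_gt(min(boreal_rows), max(temperate_rows))
})

test_that("generated plots match the configured attribute marginals", {
  land <- generate_landscape(8, 8, seed = 3)
  pl <- generate_plots(land, 1000, seed = 2)
  ba <- vapply(split(pl$stems, pl$stems$plot_id), compute_ba, numeric(1))
  expect_gte(median(ba), 24)
  expect_lte(median(ba), 30)
  expect_true(all(pl$plots$soil %in% bg_soil_classes()))
  expect_true(all(pl$plots$slope_pct %in% c(0, 4, 9, 16, 31, 41)))
  expect_true(all(pl$stems$subplot %in% c("sapling", "main", "large")))
  expect_error(generate_plots(land, 0, seed = 2), ">= 1")
})

test_that("zero-noise ring series round-trip to the truth surface exactly", {
  land <- generate_landscape(8, 8, seed = 3)
  pl <- generate_plots(land, 10, seed = 4)
  cov <- plot_covariates_from_landscape(land, pl$plots)
  truth <- ground_truth(sigma_log = 0)
  st <- pl$stems[pl$stems$plot_id == cov$plot_id[1], ]
  rs <- generate_ring_series(cov[1, ], st, truth, 5, seed = 5, sigma = 0)
  got <- vapply(rs$series, function(s) summarize_tree(s)$bai, numeric(1))
  expect_equal(got, rs$truth_table$true_bai, tolerance = 1e-6)
})

test_that("log-scale residuals of noisy series are centred on the truth", {
  land <- generate_landscape(8, 8, seed = 3)
  pl <- generate_plots(land, 40, seed = 4)
  cov <- plot_covariates_from_landscape(land, pl$plots)
  truth <- ground_truth(sigma_log = 0.3)
  res <- c()
  for (i in seq_len(nrow(cov))) {
    st <- pl$stems[pl$stems$plot_id == cov$plot_id[i], ]
    if (!any(st$dbh > 9)) next
    rs <- generate_ring_series(cov[i, ], st, truth, 4, seed = 100 + i)
    for (j in seq_along(rs$series)) {
      tab <- rings_to_bai(rs$series[[j]])
      win <- growth_window(tab$year)
      # per-ring log residuals are exactly the injected noise
      eps <- log(tab$bai[tab$year %in% win$years] + 1) -
        log(rs$truth_table$true_bai[j] + 1)
      res <- c(res, eps)
    }
  }
  expect_lt(abs(mean(res)), 3 * 0.3 / sqrt(length(res)))
})

test_that("contaminated rings are caught by the Tukey screen", {
  land <- generate_landscape(8, 8, seed = 3)
  pl <- generate_plots(land, 30, seed = 4)
  cov <- plot_covariates_from_landscape(land, pl$plots)
  truth <- ground_truth(sigma_log = 0.2)
  flagged <- 0L; total <- 0L
  for (i in seq_len(nrow(cov))) {
    st <- pl$stems[pl$stems$plot_id == cov$plot_id[i], ]
    if (!any(st$dbh > 9)) next
    rs <- generate_ring_series(cov[i, ], st, truth, 4, seed = 200 + i,
                               contamination = 0.05, outlier_factor = 8)
    for (s in rs$series) {
      tab <- rings_to_bai(s)
      win <- growth_window(tab$year)
      flags <- tukey_screen(tab$bai[tab$year %in% win$years], k = 3)
      flagged <- flagged + sum(flags)
      total <- total + length(flags)
    }
  }
  # at a 5% injection rate of 8x outliers, a nontrivial share must be caught
  expect_gt(flagged / total, 0.01)
  expect_lt(flagged / total, 0.12)
})

test_that("the coring protocol bounds the number of sampled trees", {
  land <- generate_landscape(8, 8, seed = 3)
  pl <- generate_plots(land, 2, seed = 4)
  cov <- plot_covariates_from_landscape(land, pl$plots)
  st <- pl$stems[pl$stems$plot_id == cov$plot_id[1], ]
  truth <- ground_truth()
  expect_error(generate_ring_series(cov[1, ], st, truth, 12, seed = 1),
               "3-9")
  expect_warning(generate_ring_series(cov[1, ], st, truth, 2, seed = 1,
                                      protocol = "warn"),
                 "3-9")
})

test_that("stem inventories bin into half-open 2-cm classes above 9 cm", {
  st <- data.frame(plot_id = "P1", species = "aspen",
                   dbh = runif(12, 10, 10.99), count = 1L, subplot = "main")
  inv <- generate_stem_inventory(st)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$count, 12)
  expect_equal(inv$dbh_class, 10)
  # boundary: 9.0 falls in [9, 11), 11.0 in [11, 13)
  b <- generate_stem_inventory(
    data.frame(plot_id = "P1", species = "aspen", dbh = c(9, 11),
               count = 1L, subplot = "main"))
  expect_equal(b$dbh_class, c(10, 12))
  expect_equal(unname(b$expansion), c(25, 25))
  # binned basal area stays within 2% of the exact per-stem total
  set.seed(9)
  big <- data.frame(plot_id = "P1", species = "black_spruce",
                    dbh = 9 + rgamma(5000, 1.8, scale = 4), count = 1L)
  big$subplot <- subplot_for_dbh(big$dbh)
  inv <- generate_stem_inventory(big)
  exact <- sum(pi * (big$dbh / 200)^2 * expansion_factor(big$subplot))
  binned <- sum(inv$count * pi * (inv$dbh_class / 200)^2 * inv$expansion)
  expect_lt(abs(binned - exact) / exact, 0.02)
  expect_error(generate_stem_inventory(big[0, ]), "empty")
})

test_that("full dataset simulation is reproducible under a fixed seed", {
  a <- simulate_dataset(seed = 5, n_cells_x = 6, n_cells_y = 6, n_plots = 12,
                        trees_per_plot = 3)
  b <- simulate_dataset(seed = 5, n_cells_x = 6, n_cells_y = 6, n_plots = 12,
                        trees_per_plot = 3)
  expect_identical(a$truth_table, b$truth_table)
  expect_identical(a$inventory, b$inventory)
  expect_identical(rings_to_bai(a$series[[1]]), rings_to_bai(b$series[[1]]))
})
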