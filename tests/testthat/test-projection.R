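test_that("scenario arithmetic is exact", {
  clim <- data.frame(plot_id = "P1", tmax = 5, cmi_gs = 40, prec_gs = 500)
  # null scenario is an identity
  expect_equal(apply_scenario(clim, scenario(0, 0)), clim)
  # +15% precipitation at 500 mm adds exactly 75 mm of CMI
  p <- apply_scenario(clim, scenario(0, 15))
  expect_equal(p$cmi_gs, 40 + 75)
  # 4 degC with the default coupling removes exactly 173 mm
  p <- apply_scenario(clim, scenario(4, 0))
  expect_equal(p$cmi_gs, 40 - 173)
  expect_equal(p$tmax, 9)
})

test_that("local patterns are mean-one ramps and preserve nominal changes", {
  set.seed(2)
  plots <- data.frame(plot_id = sprintf("P%d", 1:200),
                      x_km = runif(200, 0, 120), y_km = runif(200, 0, 120))
  sc <- scenario(2, 10)
  pat <- local_patterns(plots, sc)
  expect_equal(mean(pat$t), 1, tolerance = 1e-9)
  expect_equal(mean(pat$p), 1, tolerance = 1e-9)
  # warming amplified northward, precipitation increase eastward
  expect_gt(cor(pat$t, plots$y_km), 0.99)
  expect_gt(cor(pat$p, plots$x_km), 0.99)
  clim <- data.frame(plot_id = plots$plot_id, tmax = 5,
                     cmi_gs = 0, prec_gs = 500)
  pert <- apply_scenario(clim, sc, pat)
  expect_equal(mean(pert$tmax - clim$tmax), 2, tolerance = 1e-6)
  # monotone coupling: more warming never increases CMI
  pert3 <- apply_scenario(clim, scenario(3, 10), pat)
  expect_true(all(pert3$cmi_gs <= pert$cmi_gs + 1e-9))
})

test_that("stem projection reduces to the closed form for a single stem", {
  fx <- fixture_projection()
  cov <- fx$sim$plot_covariates[1, ]
  inv <- data.frame(plot_id = cov$plot_id, species = "black_spruce",
                    dbh_class = 14, count = 3L, subplot = "main",
                    expansion = 25)
  res <- project_stems(fx$models, inv, cov, cov)
  nd <- data.frame(size = 14, age = cov$stand_age, ba = inventory_ba_ref(inv),
                   bal = 0, slope = cov$slope_pct, soil = cov$soil,
                   snow = as.character(classify_snow(cov$snow_jfm)),
                   stage = as.character(classify_stage(cov$stand_age)),
                   tmax = cov$tmax, cmi_gs = cov$cmi_gs)
  expect_equal(res$growth,
               3 * predict_bai(fx$models$black_spruce, nd) * 25,
               tolerance = 1e-9)
  # identical climates give identical growth
  res2 <- project_stems(fx$models, inv, cov, cov)
  expect_identical(res, res2)
  # species without a model are skipped and tallied
  inv2 <- rbind(inv, transform(inv, species = "larch"))
  res3 <- project_stems(fx$models, inv2, cov, cov)
  expect_equal(sum(attr(res3, "skipped")), 3)
  expect_error(project_stems(list(), inv, cov, cov), "no stem")
})

test_that("polygon aggregation is an unweighted per-cell mean", {
  pv <- data.frame(x_km = c(1, 5, 9, 20, 22), y_km = c(1, 2, 3, 40, 44),
                   g = c(1, 2, 3, 10, 30))
  agg <- aggregate_polygons(pv, "g", grid_km = 15)
  expect_equal(nrow(agg), 2)
  expect_equal(sort(agg$g), c(2, 20))
  expect_equal(sort(agg$n_plots), c(2, 3))
  # duplicating every plot leaves polygon means unchanged
  agg2 <- aggregate_polygons(rbind(pv, pv), "g", grid_km = 15)
  expect_equal(agg$g, agg2$g)
  # disjoint cells are independent
  agg3 <- aggregate_polygons(pv[1:3, ], "g", grid_km = 15)
  expect_equal(agg3$g, agg$g[agg$n_plots == 3])
})

test_that("zone summaries report mean, SE and decline fraction over polygons", {
  z <- zone_summary(data.frame(baseline = c(100, 100),
                               scenario = c(110, 90)))
  expect_equal(z$mean_change_pct, 0)
  expect_equal(z$fraction_declining, 0.5)
  expect_equal(z$n_polygons, 2)
  expect_equal(z$se_change_pct, stats::sd(c(10, -10)) / sqrt(2))
  z2 <- zone_summary(data.frame(baseline = c(10, 10, 10),
                                scenario = c(11, 12, 13)))
  expect_equal(z2$fraction_declining, 0)
  expect_error(zone_summary(data.frame(baseline = numeric(0),
                                       scenario = numeric(0))), "no polygons")
})

test_that("species-summed aggregation is linear", {
  # with every species present in every plot, summing species before
  # aggregating equals summing the per-species polygon means
  set.seed(5)
  pv <- expand.grid(plot_id = sprintf("P%d", 1:12),
                    species = c("a", "b"), stringsAsFactors = FALSE)
  pv$x_km <- rep(runif(12, 0, 60), 2)
  pv$y_km <- rep(runif(12, 0, 60), 2)
  pv$growth <- runif(nrow(pv), 1, 100)
  per_sp <- aggregate_polygons(pv, "growth", grid_km = 15, by = "species")
  summed <- stats::aggregate(growth ~ plot_id + x_km + y_km, data = pv,
                             FUN = sum)
  combined <- aggregate_polygons(summed, "growth", grid_km = 15)
  merged <- stats::aggregate(growth ~ polygon_id, data = per_sp, FUN = sum)
  merged <- merged[order(merged$polygon_id), ]
  expect_equal(merged$growth, combined$growth[order(combined$polygon_id)])
})

test_that("the climate-space guard tracks the observed temperature range", {
  fx <- fixture_projection()
  cov <- fx$sim$plot_covariates
  inv <- fx$sim$inventory
  obs_max <- c(black_spruce = fx$models$black_spruce$ranges$temp[2])
  base <- climate_space_guard(inv, cov, obs_max)
  expect_equal(unname(base["black_spruce"]), 1)
  hot <- apply_scenario(cov, scenario(50, 0))
  expect_equal(unname(climate_space_guard(inv, hot, obs_max)["black_spruce"]),
               0)
  mid <- apply_scenario(cov, scenario(4, 0))
  frac <- climate_space_guard(inv, mid, obs_max)["black_spruce"]
  expect_gte(frac, 0)
  expect_lte(frac, 1)
})
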