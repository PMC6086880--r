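test_that("a linear moisture truth yields a near-linear fitted CMI smooth", {
  truth <- ground_truth(temperature_response = "linear",
                        moisture_response = "linear", sigma_log = 0.2)
  obs <- synth_obs(1200, truth, seed = 11)
  m <- fit_growth_model(obs, model_spec(factor_smooths = FALSE,
                                        engine = "gam"))
  sm <- summary(m$fit)
  edf_cmi <- sm$s.table[grep("s\\(cmiv\\)", rownames(sm$s.table))[1], "edf"]
  expect_lt(edf_cmi, 1.6)
  # monotone decreasing partial effect, as generated
  pe <- partial_effect(m, "cmiv", n = 30)
  expect_lt(pe$bai[30], pe$bai[1])
  expect_gt(mean(diff(pe$bai) < 0), 0.9)
  # linear-regression oracle agrees on the direction and rough magnitude
  lin <- stats::lm(log(bai + 1) ~ cmi_gs, data = obs)
  expect_lt(coef(lin)["cmi_gs"], 0)
})

test_that("the fitted temperature optimum recovers the generating threshold", {
  fx <- fixture_recovery()
  expect_lt(abs(fitted_t_opt(fx$model) - 8), 0.6)
  # partial-effect surface over temperature x moisture has an interior max
  pe <- partial_effect(fx$model, c("temp", "cmiv"), n = 25)
  best <- pe[which.max(pe$bai), ]
  expect_gt(best$temp, min(pe$temp))
  expect_lt(best$temp, max(pe$temp))
})

test_that("no smooth exceeds its declared basis bound", {
  fx <- fixture_recovery()
  sm <- summary(fx$model$fit)
  edf <- sm$s.table[, "edf"]
  tensor <- grepl("^te\\(", rownames(sm$s.table))
  expect_true(all(edf[!tensor] <= 4 - 1 + 1e-6))
  expect_true(all(edf[tensor] <= 3 * 3 - 1 + 1e-6))
})

test_that("constant-response data collapse to intercept-only predictions", {
  truth <- ground_truth(sigma_log = 0)
  obs <- synth_obs(300, truth, seed = 4, sigma = 0)
  obs$bai <- 5
  m <- fit_growth_model(obs, model_spec(factor_smooths = FALSE,
                                        engine = "gam"))
  pred <- predict_bai(m, obs)
  expect_lt(max(abs(pred - 5)), 0.05)
  expect_equal(unname(m$smearing), 1, tolerance = 1e-6)
})

test_that("the smearing factor obeys the lognormal moment identity", {
  expect_equal(smearing_factor(rep(0, 10)), 1)
  set.seed(8)
  for (s in c(0.2, 0.5)) {
    r <- rnorm(1e5, 0, s)
    expect_equal(smearing_factor(r), exp(s^2 / 2), tolerance = 0.01)
  }
  expect_error(smearing_factor(0.5), ">= 2")
  expect_error(smearing_factor(c(1, Inf)), "non-finite")
})

test_that("smeared back-transform is mean-unbiased where the naive one is low", {
  set.seed(15)
  n <- 2e4
  mu <- 2
  y <- exp(mu + rnorm(n, 0, 0.5))
  s <- smearing_factor(log(y) - mu)
  naive <- exp(mu)
  smeared <- exp(mu) * s
  expect_lt(naive, mean(y) * 0.95)
  expect_equal(smeared, mean(y), tolerance = 0.02)
})

test_that("prediction is deterministic and validates its inputs", {
  fx <- fixture_recovery()
  nd <- fx$obs[1:5, ]
  expect_identical(predict_bai(fx$model, nd), predict_bai(fx$model, nd))
  expect_error(predict_bai(fx$model, nd[setdiff(names(nd), "ba")]), "'ba'")
  nd2 <- nd
  nd2$soil <- "shallow_hydric_unseen"
  expect_warning(predict_bai(fx$model, nd2), "folded")
  # training rows reproduce the observed response well at sigma = 0.3
  pred <- predict_bai(fx$model, fx$obs)
  r2 <- cor(log(pred + 1), log(fx$obs$bai + 1))^2
  expect_gt(r2, 0.8)
})

test_that("AIC climate-variable selection breaks exact ties by declared order", {
  truth <- ground_truth(sigma_log = 0.2)
  obs <- synth_obs(400, truth, seed = 21)
  obs$tmean <- obs$tmax
  obs$cmi_summer <- obs$cmi_gs
  sel <- select_climate_variables(obs, model_spec(factor_smooths = FALSE,
                                                  engine = "gam"))
  expect_equal(sel$best, c("tmax", "cmi_gs"))
  expect_equal(nrow(sel$table), 4)
  expect_lt(diff(range(sel$table$aic)), 1e-6)
})

test_that("validation reaches its noiseless and pure-noise limits", {
  clean <- synth_obs_representable(800, seed = 31)
  # REML step warnings are expected as the residual scale approaches zero
  v <- suppressWarnings(
    validate_growth_model(clean, model_spec(factor_smooths = FALSE,
                                            engine = "gam"), seed = 1))
  expect_gt(v$dev_expl, 99.9)
  expect_lt(v$test_rmse_pct, 1)
  noise <- clean
  set.seed(32)
  noise$bai <- rlnorm(nrow(noise), 1.5, 0.5)
  v2 <- validate_growth_model(noise, model_spec(factor_smooths = FALSE,
                                                engine = "gam"), seed = 1)
  expect_lt(v2$dev_expl, 5)
  # moderate noise: train and test error comparable (no gross overfit)
  mid <- synth_obs(2000, ground_truth(sigma_log = 0.3), seed = 33)
  v3 <- validate_growth_model(mid, model_spec(factor_smooths = FALSE,
                                              engine = "gam"), seed = 1)
  expect_lt(abs(v3$test_rmse_pct - v3$rmse_pct) / v3$rmse_pct, 0.15)
})

test_that("model export writes a readable JSON summary", {
  fx <- fixture_recovery()
  path <- withr::local_tempfile(fileext = ".json")
  export_model_json(fx$model, path)
  obj <- jsonlite::read_json(path)
  expect_true(all(c("coefficients", "smearing", "metrics", "center") %in%
                    names(obj)))
  expect_equal(obj$metrics$n, nrow(fx$obs))
})
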