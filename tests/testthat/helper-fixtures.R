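# Shared, lazily built simulation fixtures. Heavy objects are built once
# per test run and cached, so several test files can reuse the same fitted
# model without refitting.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# moderate-size single-species dataset from a unimodal truth at 8 degC,
# with its fitted model
fixture_recovery <- function() {
  with_cache("recovery", function() {
    truth <- ground_truth(t_opt = 8, sigma_log = 0.3)
    sim <- simulate_dataset(seed = 2024, n_cells_x = 12, n_cells_y = 12,
                            n_plots = 400, trees_per_plot = 4, truth = truth,
                            species_probs = c(black_spruce = 1))
    prep <- prepare_tree_observations(sim$series, sim$plot_covariates,
                                      sim$stems)
    model <- fit_growth_model(prep$observations, model_spec())
    list(sim = sim, obs = prep$observations, model = model, truth = truth)
  })
}

# end-to-end projection fixture: mid-gradient optimum truth (5 degC, the
# middle of the boreal T_MAX span), fitted model and stem inventory
fixture_projection <- function() {
  with_cache("projection", function() {
    truth <- ground_truth(t_opt = 5, sigma_log = 0.3)
    sim <- simulate_dataset(seed = 77, n_cells_x = 12, n_cells_y = 12,
                            n_plots = 400, trees_per_plot = 5, truth = truth,
                            species_probs = c(black_spruce = 1))
    prep <- prepare_tree_observations(sim$series, sim$plot_covariates,
                                      sim$stems)
    model <- fit_growth_model(prep$observations, model_spec())
    list(sim = sim, obs = prep$observations,
         models = list(black_spruce = model), truth = truth)
  })
}

# observation table whose log-response lies exactly in the model span
# (linear in every covariate): the perfect-fit limit of the growth model
synth_obs_representable <- function(n, seed, sigma = 0) {
  set.seed(seed)
  covars <- data.frame(
    size = runif(n, 10, 30),
    age = runif(n, 25, 120),
    ba = runif(n, 10, 60),
    bal = runif(n, 0, 35),
    slope = sample(c(0, 4, 9, 16, 31, 41), n, replace = TRUE),
    tmax = runif(n, 0, 12),
    cmi_gs = runif(n, -200, 250),
    soil = sample(bg_soil_classes(), n, replace = TRUE),
    snow = sample(bg_snow_classes(), n, replace = TRUE),
    stage = sample(bg_stages(), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  covars$tmean <- covars$tmax - 5.5
  covars$cmi_summer <- 0.6 * covars$cmi_gs
  eta <- 0.4 + 0.5 * log(covars$size) + 0.01 * covars$size -
    0.004 * covars$age - 0.006 * covars$ba - 0.01 * covars$bal -
    0.003 * covars$slope + 0.05 * covars$tmax + 0.001 * covars$cmi_gs
  covars$bai <- exp(eta + rnorm(n, 0, sigma)) - 1
  covars
}

# per-hectare basal area implied by a class inventory (reference formula)
inventory_ba_ref <- function(inv) {
  sum(inv$count * pi * (inv$dbh_class / 200)^2 * inv$expansion)
}

# small stem table used across stand/projection unit tests
toy_stems <- function() {
  data.frame(
    plot_id = "P1",
    species = c("black_spruce", "black_spruce", "balsam_fir", "balsam_fir"),
    dbh = c(12, 20, 5, 35),
    count = c(3L, 1L, 2L, 1L),
    subplot = c("main", "main", "sapling", "large"),
    stringsAsFactors = FALSE
  )
}

# quick synthetic observation table driven directly by a truth surface
# (no ring-series machinery), for model-level tests
synth_obs <- function(n, truth, seed, sigma = truth$sigma_log) {
  set.seed(seed)
  soil <- sample(bg_soil_classes(), n, replace = TRUE)
  snow <- sample(bg_snow_classes(), n, replace = TRUE)
  stage <- sample(bg_stages(), n, replace = TRUE)
  covars <- data.frame(
    size = runif(n, 10, 30),
    age = runif(n, 25, 120),
    ba = runif(n, 10, 60),
    bal = runif(n, 0, 35),
    slope = sample(c(0, 4, 9, 16, 31, 41), n, replace = TRUE),
    tmax = runif(n, 0, 12),
    cmi_gs = runif(n, -200, 250),
    soil = soil, snow = snow, stage = stage,
    stringsAsFactors = FALSE
  )
  covars$tmean <- covars$tmax - 5.5 + rnorm(n, 0, 1)
  covars$cmi_summer <- 0.6 * covars$cmi_gs + rnorm(n, 0, 25)
  g <- eval_truth(truth, covars)
  covars$bai <- pmax(0, (g + 1) * exp(rnorm(n, 0, sigma)) - 1)
  covars$true_bai <- g
  covars
}
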