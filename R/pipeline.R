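# Pipeline orchestration: staged runs (simulate / prepare / fit / project /
# report) driven by a validated configuration, with plain CSV/JSON
# artifacts and a run manifest for reproducibility.

default_config <- function() {
  list(
    seed = 1L,
    outdir = "bg_run",
    # synthetic generation
    n_cells_x = 12L, n_cells_y = 12L, cell_km = 10,
    n_plots = 150L, trees_per_plot = 4L,
    sigma = NULL, contamination = 0,
    truth = list(),            # overrides passed to ground_truth()
    # model options
    species = NULL,            # NULL = every species with enough trees
    min_obs = 50L,
    basis_dim = 4L, tensor_dim = 3L, factor_smooths = TRUE,
    temperature_var = "tmax", moisture_var = "cmi_gs",
    method = "REML", engine = "auto",
    # projection options
    grid_km = 15, zone = "boreal",
    pet_coupling = 43.25,
    pattern_t_strength = 0.3, pattern_p_strength = 0.5,
    scenarios = NULL           # NULL = default_scenario_grid()
  )
}

#' Read and validate a run configuration
#'
#' Merges user settings (a named list, or a YAML file path) over the
#' defaults. Unknown keys are rejected.
#'
#' @param config Named list or path to a YAML file; `NULL` gives defaults.
#' @return Validated configuration list of class `bg_config`.
#' @export
read_run_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0L) {
    stopf("read_run_config: unknown configuration key(s): %s",
          paste(unknown, collapse = ", "))
  }
  base[names(config)] <- config
  structure(base, class = "bg_config")
}

artifact_path <- function(config, name) file.path(config$outdir, name)

require_artifact <- function(config, name, producer) {
  p <- artifact_path(config, name)
  if (!file.exists(p)) {
    stopf("missing artifact '%s'; run the '%s' stage first", p, producer)
  }
  p
}

write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

# flatten ring series to the long rings.csv schema and back
rings_to_long <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s) {
    data.frame(tree_id = s$tree_id, plot_id = s$plot_id, species = s$species,
               sampling_year = s$sampling_year, dbh_cm = s$dbh_cm,
               outer_lag = s$outer_lag, year = s$years,
               width_mm = s$width_mm, stringsAsFactors = FALSE)
  }))
}

rings_from_long <- function(df) {
  lapply(split(df, df$tree_id), function(d) {
    ring_series(d$tree_id[1], d$plot_id[1], d$species[1], d$dbh_cm[1],
                d$sampling_year[1], d$year, d$width_mm,
                outer_lag = d$outer_lag[1])
  })
}

#' Run one pipeline stage
#'
#' Stages:
#' \describe{
#'   \item{simulate}{Generate the synthetic landscape, plots, ring series
#'     and stem inventory; writes `rings.csv`, `stems.csv`,
#'     `plot_covariates.csv`, `inventory.csv` and `ground_truth.json`.}
#'   \item{prepare}{Convert ring series to model-ready tree observations
#'     (`tree_obs.csv`).}
#'   \item{fit}{Fit the growth model per species; writes
#'     `model_<species>.json`, `fit_report.csv` and `models.rds` (runtime
#'     object for the project stage).}
#'   \item{project}{Apply the scenario grid to the stem inventory; writes
#'     `zone_summary.csv` and `projection_polygons.csv`.}
#'   \item{report}{Re-reads the fit and projection artifacts and prints the
#'     fit-summary and projection tables; writes `manifest.json`.}
#' }
#'
#' @param stage One of `"simulate"`, `"prepare"`, `"fit"`, `"project"`,
#'   `"report"`, or `"all"` to run the full chain.
#' @param config Passed to [read_run_config()].
#' @return The stage's main result, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "prepare", "fit",
                                   "project", "report"),
                         config = NULL) {
  stage <- match.arg(stage)
  config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    for (s in c("simulate", "prepare", "fit", "project", "report")) {
      out <- run_pipeline(s, unclass(config))
    }
    return(invisible(out))
  }
  switch(stage,
         simulate = stage_simulate(config),
         prepare = stage_prepare(config),
         fit = stage_fit(config),
         project = stage_project(config),
         report = stage_report(config))
}

stage_simulate <- function(config) {
  truth <- do.call(ground_truth, config$truth)
  sim <- simulate_dataset(seed = config$seed,
                          n_cells_x = config$n_cells_x,
                          n_cells_y = config$n_cells_y,
                          cell_km = config$cell_km,
                          n_plots = config$n_plots,
                          trees_per_plot = config$trees_per_plot,
                          truth = truth, sigma = config$sigma,
                          contamination = config$contamination)
  write_csv_atomic(rings_to_long(sim$series), artifact_path(config, "rings.csv"))
  write_csv_atomic(sim$stems, artifact_path(config, "stems.csv"))
  write_csv_atomic(sim$plot_covariates,
                   artifact_path(config, "plot_covariates.csv"))
  write_csv_atomic(sim$inventory, artifact_path(config, "inventory.csv"))
  write_csv_atomic(sim$truth_table, artifact_path(config, "truth_table.csv"))
  jsonlite::write_json(
    list(parameters = unclass(sim$truth), seed = config$seed),
    artifact_path(config, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("simulate: %d plots, %d trees, %d inventory records",
                  nrow(sim$plot_covariates), length(sim$series),
                  nrow(sim$inventory)))
  invisible(sim)
}

stage_prepare <- function(config) {
  rings <- utils::read.csv(require_artifact(config, "rings.csv", "simulate"))
  stems <- utils::read.csv(require_artifact(config, "stems.csv", "simulate"))
  cov <- utils::read.csv(require_artifact(config, "plot_covariates.csv",
                                          "simulate"))
  series <- rings_from_long(rings)
  prep <- prepare_tree_observations(series, cov, stems)
  write_csv_atomic(prep$observations, artifact_path(config, "tree_obs.csv"))
  message(sprintf("prepare: kept %d of %d trees",
                  prep$dropped$n_kept, prep$dropped$n_input))
  invisible(prep)
}

stage_fit <- function(config) {
  obs <- utils::read.csv(require_artifact(config, "tree_obs.csv", "prepare"))
  spec <- model_spec(basis_dim = config$basis_dim,
                     tensor_dim = config$tensor_dim,
                     factor_smooths = config$factor_smooths,
                     temperature_var = config$temperature_var,
                     moisture_var = config$moisture_var,
                     method = config$method, engine = config$engine)
  species <- config$species %||% names(which(table(obs$species) >= config$min_obs))
  if (length(species) == 0L) stopf("fit: no species with >= %d trees",
                                   config$min_obs)
  models <- list(); report <- list()
  for (sp in species) {
    d <- obs[obs$species == sp, , drop = FALSE]
    models[[sp]] <- fit_growth_model(d, spec, min_obs = config$min_obs)
    export_model_json(models[[sp]],
                      artifact_path(config, sprintf("model_%s.json", sp)))
    report[[sp]] <- cbind(species = sp, models[[sp]]$metrics)
  }
  rep_df <- do.call(rbind, report)
  write_csv_atomic(rep_df, artifact_path(config, "fit_report.csv"))
  saveRDS(models, artifact_path(config, "models.rds"))
  message(sprintf("fit: %d species model(s): %s",
                  length(models), paste(species, collapse = ", ")))
  invisible(models)
}

stage_project <- function(config) {
  models <- readRDS(require_artifact(config, "models.rds", "fit"))
  inv <- utils::read.csv(require_artifact(config, "inventory.csv", "simulate"))
  cov <- utils::read.csv(require_artifact(config, "plot_covariates.csv",
                                          "simulate"))
  scen <- config$scenarios %||% default_scenario_grid()
  if (!is.data.frame(scen)) scen <- as.data.frame(scen)
  res <- project_growth_change(models, inv, cov, scenarios = scen,
                               zone = config$zone, grid_km = config$grid_km,
                               pet_coupling = config$pet_coupling,
                               pattern_t_strength = config$pattern_t_strength,
                               pattern_p_strength = config$pattern_p_strength)
  write_csv_atomic(res$summary, artifact_path(config, "zone_summary.csv"))
  write_csv_atomic(res$polygons,
                   artifact_path(config, "projection_polygons.csv"))
  guard_df <- do.call(rbind, lapply(names(res$guard), function(k) {
    data.frame(scenario = k, species = names(res$guard[[k]]),
               fraction_in_range = unname(res$guard[[k]]))
  }))
  write_csv_atomic(guard_df, artifact_path(config, "climate_guard.csv"))
  message(sprintf("project: %d scenario(s) x %d species rows",
                  nrow(scen), nrow(res$summary)))
  invisible(res)
}

stage_report <- function(config) {
  fit_rep <- utils::read.csv(require_artifact(config, "fit_report.csv", "fit"))
  zone <- utils::read.csv(require_artifact(config, "zone_summary.csv",
                                           "project"))
  manifest <- list(package_version = as.character(utils::packageVersion("borealgrowth")),
                   config = unclass(config))
  jsonlite::write_json(manifest, artifact_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  cat("== Model fit summary ==\n")
  print(fit_rep, row.names = FALSE)
  cat("\n== Projected growth change (zone means) ==\n")
  print(zone, row.names = FALSE)
  invisible(list(fit = fit_rep, zone = zone))
}
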