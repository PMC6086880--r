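# Scenario projection: perturb plot climate under warming / precipitation
# scenarios with locally varying patterns, predict stem-inventory growth,
# aggregate to 15-km polygons and summarise over the boreal zone.

#' Define a climate-change scenario
#'
#' A scenario is a nominal (area-mean) increase in T_MAX, a nominal change
#' in growing-season precipitation (percent), and a PET coupling that
#' converts local warming into an increase of potential evapotranspiration.
#' The default linear coupling of 43.25 mm per degC reproduces the 43-173 mm
#' PET increase associated with 1-4 degC of warming.
#'
#' @param dt Nominal T_MAX increase, degC.
#' @param dp_pct Nominal growing-season precipitation change, percent.
#' @param pet_coupling PET increase per degC of local warming, mm.
#' @param pattern_t_strength,pattern_p_strength Amplitudes of the local
#'   pattern ramps (warming amplified toward high latitude, precipitation
#'   increase toward the east edge); 0 gives uniform change.
#' @return Object of class `bg_scenario`.
#' @export
scenario <- function(dt, dp_pct, pet_coupling = 43.25,
                     pattern_t_strength = 0.3, pattern_p_strength = 0.5) {
  structure(list(dt = dt, dp_pct = dp_pct, pet_coupling = pet_coupling,
                 pattern_t_strength = pattern_t_strength,
                 pattern_p_strength = pattern_p_strength),
            class = "bg_scenario")
}

#' Local scenario pattern fields
#'
#' Dimensionless multipliers, one per plot, normalised to an exact mean of
#' 1 over the supplied plots: warming amplification increases linearly
#' along the latitude-like (y) axis, precipitation increase along the
#' longitude-like (x) axis.
#'
#' @param plots Data.frame with `x_km` and `y_km`.
#' @param scen A [scenario()].
#' @return List with numeric vectors `t` and `p` (each mean exactly 1).
#' @export
local_patterns <- function(plots, scen) {
  ramp <- function(coord, strength) {
    r <- range(coord)
    frac <- if (diff(r) > 0) (coord - r[1]) / diff(r) else rep(0.5, length(coord))
    v <- 1 + strength * (frac - mean(frac))
    v / mean(v)
  }
  list(t = ramp(plots$y_km, scen$pattern_t_strength),
       p = ramp(plots$x_km, scen$pattern_p_strength))
}

#' Apply a scenario to plot climate summaries
#'
#' Perturbs T_MAX by the locally scaled warming and CMI by the locally
#' scaled precipitation change minus the PET increase coupled to local
#' warming:
#' `tmax' = tmax + dt * pat_t` and
#' `cmi' = cmi + prec_gs * (dp_pct * pat_p) / 100 - coupling * dt * pat_t`.
#' All other fields are unchanged.
#'
#' @param climate Data.frame of per-plot climate with columns `tmax`,
#'   `cmi_gs`, `prec_gs` (and optionally others, carried through).
#' @param scen A [scenario()].
#' @param pattern Optional list as returned by [local_patterns()]; by
#'   default uniform patterns (all 1) are used.
#' @return The climate data.frame with perturbed `tmax` and `cmi_gs`.
#' @export
apply_scenario <- function(climate, scen, pattern = NULL) {
  assert_cols(climate, c("tmax", "cmi_gs", "prec_gs"), "plot climate")
  n <- nrow(climate)
  if (is.null(pattern)) pattern <- list(t = rep(1, n), p = rep(1, n))
  if (length(pattern$t) != n || length(pattern$p) != n) {
    stopf("apply_scenario: pattern length does not match plots")
  }
  dt_local <- scen$dt * pattern$t
  out <- climate
  out$tmax <- climate$tmax + dt_local
  out$cmi_gs <- climate$cmi_gs +
    climate$prec_gs * (scen$dp_pct * pattern$p) / 100 -
    scen$pet_coupling * dt_local
  out
}

#' Project stem-inventory growth under baseline and scenario climate
#'
#' Predicts the BAI of every inventory stem class with the species' fitted
#' model, using the class midpoint as tree size, the stand mean age as tree
#' age, BAL computed from the (all-species) class table against each stem's
#' midpoint, and the plot's BA, soil, snowfall, slope and stage; growth per
#' hectare is the count- and expansion-weighted sum of stem BAI. Species
#' without a fitted model are skipped and tallied.
#'
#' @param models Named list of [fit_growth_model()] objects, keyed by
#'   species.
#' @param inventory 2-cm class stem inventory (see
#'   [generate_stem_inventory()]).
#' @param plot_covariates Per-plot covariates including `plot_id`, `x_km`,
#'   `y_km`, `zone`, `slope_pct`, `soil`, `snow_jfm`, `stand_age`.
#' @param climate Per-plot climate (`plot_id`, `tmax`, `cmi_gs`, `prec_gs`,
#'   ...), typically columns of `plot_covariates` or an
#'   [apply_scenario()] output.
#' @param plot_ba Optional named vector of plot BA (m2 ha-1); computed from
#'   the inventory when absent.
#' @return Data.frame with one row per plot and species: `plot_id`,
#'   `species`, `x_km`, `y_km`, `zone`, `growth` (cm2 ha-1), plus an
#'   attribute `skipped` tallying stems without a model.
#' @export
project_stems <- function(models, inventory, plot_covariates, climate,
                          plot_ba = NULL) {
  assert_cols(inventory, c("plot_id", "species", "dbh_class", "count",
                           "expansion"), "inventory")
  cov_idx <- match(inventory$plot_id, plot_covariates$plot_id)
  if (anyNA(cov_idx)) stopf("project_stems: covariates missing for some plots")
  cl_idx <- match(inventory$plot_id, climate$plot_id)
  if (anyNA(cl_idx)) stopf("project_stems: climate missing for some plots")

  inv <- inventory
  inv$stand_age <- plot_covariates$stand_age[cov_idx]
  inv$slope <- plot_covariates$slope_pct[cov_idx]
  inv$soil <- plot_covariates$soil[cov_idx]
  inv$snow <- as.character(classify_snow(plot_covariates$snow_jfm[cov_idx]))
  inv$stage <- as.character(classify_stage(inv$stand_age))
  inv$age <- inv$stand_age
  inv$size <- inv$dbh_class
  inv$tmax <- climate$tmax[cl_idx]
  inv$tmean <- if (!is.null(climate$tmean)) climate$tmean[cl_idx] else NA_real_
  inv$cmi_gs <- climate$cmi_gs[cl_idx]
  inv$cmi_summer <- if (!is.null(climate$cmi_summer))
    climate$cmi_summer[cl_idx] else NA_real_

  # per-plot BA and per-stem BAL from the class table (strictly larger)
  split_inv <- split(seq_len(nrow(inv)), inv$plot_id)
  inv$ba <- NA_real_; inv$bal <- NA_real_
  for (rows in split_inv) {
    sub <- inv[rows, ]
    contrib <- sub$count * stem_ba_m2(sub$dbh_class) * sub$expansion
    inv$ba[rows] <- if (!is.null(plot_ba)) {
      plot_ba[[as.character(sub$plot_id[1])]]
    } else {
      sum(contrib)
    }
    inv$bal[rows] <- vapply(sub$dbh_class,
                            function(d) sum(contrib[sub$dbh_class > d]),
                            numeric(1))
  }

  no_model <- !(inv$species %in% names(models))
  skipped <- if (any(no_model)) {
    tapply(inv$count[no_model], inv$species[no_model], sum)
  } else {
    integer(0)
  }
  keep <- inv$species %in% names(models)
  inv <- inv[keep, , drop = FALSE]
  cov_idx <- cov_idx[keep]
  if (nrow(inv) == 0L) stopf("project_stems: no stem has a fitted model")

  inv$bai_pred <- NA_real_
  for (sp in unique(inv$species)) {
    r <- inv$species == sp
    inv$bai_pred[r] <- predict_bai(models[[sp]], inv[r, , drop = FALSE])
  }
  inv$growth_contrib <- inv$count * pmax(inv$bai_pred, 0) * inv$expansion

  agg <- stats::aggregate(growth_contrib ~ plot_id + species, data = inv,
                          FUN = sum)
  names(agg)[names(agg) == "growth_contrib"] <- "growth"
  pidx <- match(agg$plot_id, plot_covariates$plot_id)
  agg$x_km <- plot_covariates$x_km[pidx]
  agg$y_km <- plot_covariates$y_km[pidx]
  agg$zone <- plot_covariates$zone[pidx]
  attr(agg, "skipped") <- skipped
  agg[order(agg$plot_id, agg$species), ]
}

#' Aggregate plot values over a square-km grid
#'
#' Bins plots into grid cells of `grid_km` edge (half-open bins on both
#' axes) and returns the unweighted mean of each value column per cell.
#' Cells containing no plots are absent from the output.
#'
#' @param plot_values Data.frame with `x_km`, `y_km` and numeric value
#'   columns.
#' @param value_cols Names of the columns to average.
#' @param grid_km Grid size, default 15.
#' @param by Optional extra grouping columns (e.g. `"species"`).
#' @return Data.frame with `polygon_id`, grid indices, `n_plots` and the
#'   averaged columns.
#' @export
aggregate_polygons <- function(plot_values, value_cols, grid_km = 15,
                               by = NULL) {
  assert_cols(plot_values, c("x_km", "y_km", value_cols, by), "plot values")
  pv <- plot_values
  pv$.gx <- floor(pv$x_km / grid_km)
  pv$.gy <- floor(pv$y_km / grid_km)
  pv$polygon_id <- sprintf("G%d_%d", pv$.gx, pv$.gy)
  keys <- c("polygon_id", ".gx", ".gy", by)
  agg <- stats::aggregate(pv[value_cols], pv[keys], FUN = mean)
  cnt <- stats::aggregate(list(n_plots = pv$x_km), pv[keys], FUN = length)
  out <- merge(agg, cnt, by = keys)
  names(out)[names(out) == ".gx"] <- "grid_x"
  names(out)[names(out) == ".gy"] <- "grid_y"
  out[order(out$polygon_id), ]
}

#' Summarise polygon-level growth change over a zone
#'
#' Relative change per polygon is `(scenario - baseline) / baseline * 100`;
#' the zone summary is the mean and standard error of the polygon changes,
#' the fraction of polygons with a decline (change < 0), and the polygon
#' count.
#'
#' @param polygons Data.frame with `baseline` and `scenario` growth columns.
#' @return List with `mean_change_pct`, `se_change_pct`,
#'   `fraction_declining`, `n_polygons`, and the per-polygon `changes`.
#' @export
zone_summary <- function(polygons) {
  assert_cols(polygons, c("baseline", "scenario"), "polygon growth")
  if (nrow(polygons) == 0L) stopf("zone_summary: no polygons")
  ch <- (polygons$scenario - polygons$baseline) / polygons$baseline * 100
  n <- length(ch)
  list(mean_change_pct = mean(ch),
       se_change_pct = if (n > 1) stats::sd(ch) / sqrt(n) else 0,
       fraction_declining = mean(ch < 0),
       n_polygons = n,
       changes = ch)
}

#' Climate-space guard
#'
#' For each species, the (count-weighted) fraction of inventory stems whose
#' perturbed T_MAX stays at or below the species' maximum observed T_MAX in
#' the model-fitting data. Projections are trustworthy where this fraction
#' is near 1.
#'
#' @param inventory 2-cm class stem inventory.
#' @param perturbed_climate Per-plot climate after [apply_scenario()]
#'   (`plot_id`, `tmax`).
#' @param observed_tmax_max Named vector: per-species maximum T_MAX observed
#'   during fitting.
#' @return Named numeric vector of in-range fractions per species.
#' @export
climate_space_guard <- function(inventory, perturbed_climate,
                                observed_tmax_max) {
  idx <- match(inventory$plot_id, perturbed_climate$plot_id)
  if (anyNA(idx)) stopf("climate_space_guard: climate missing for some plots")
  tm <- perturbed_climate$tmax[idx]
  out <- vapply(names(observed_tmax_max), function(sp) {
    r <- inventory$species == sp
    if (!any(r)) return(NA_real_)
    stats::weighted.mean(tm[r] <= observed_tmax_max[[sp]],
                         w = inventory$count[r])
  }, numeric(1))
  out
}

#' Default scenario grid
#'
#' The cross of 1-4 degC warming with growing-season precipitation changes
#' of -5, 0 (baseline), +5 and +15 percent.
#'
#' @return Data.frame with columns `dt` and `dp_pct`.
#' @export
default_scenario_grid <- function() {
  expand.grid(dt = 1:4, dp_pct = c(-5, 0, 5, 15))
}

#' Project growth change over a scenario grid
#'
#' End-to-end projection: for every scenario, perturbs the plot climate
#' with locally varying patterns, predicts inventory growth, aggregates to
#' `grid_km` polygons (per species and for all species combined) and
#' summarises the relative change over the zone.
#'
#' @param models Named list of fitted species models.
#' @param inventory 2-cm class stem inventory.
#' @param plot_covariates Per-plot covariates (must include the climate
#'   summary columns).
#' @param scenarios Data.frame with `dt`, `dp_pct` rows
#'   (default [default_scenario_grid()]).
#' @param zone Restrict to plots of this zone (default `"boreal"`; `NULL`
#'   keeps all plots).
#' @param grid_km Aggregation grid size, default 15.
#' @param pet_coupling,pattern_t_strength,pattern_p_strength Passed to
#'   [scenario()].
#' @return List with `summary` (data.frame: one row per scenario and
#'   species, plus `"all"` for the combined total), `polygons` (per-scenario
#'   polygon tables) and `guard` (per-scenario in-range fractions).
#' @export
project_growth_change <- function(models, inventory, plot_covariates,
                                  scenarios = default_scenario_grid(),
                                  zone = "boreal", grid_km = 15,
                                  pet_coupling = 43.25,
                                  pattern_t_strength = 0.3,
                                  pattern_p_strength = 0.5) {
  pc <- plot_covariates
  if (!is.null(zone)) pc <- pc[pc$zone %in% zone, , drop = FALSE]
  if (nrow(pc) == 0L) stopf("project_growth_change: no plots in zone")
  inv <- inventory[inventory$plot_id %in% pc$plot_id, , drop = FALSE]

  baseline <- project_stems(models, inv, pc, pc)
  base_all <- stats::aggregate(growth ~ plot_id + x_km + y_km, data = baseline,
                               FUN = sum)
  obs_max <- vapply(models, function(m) m$ranges$temp[2], numeric(1))

  summaries <- list(); polys <- list(); guards <- list()
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenario(scenarios$dt[i], scenarios$dp_pct[i],
                   pet_coupling = pet_coupling,
                   pattern_t_strength = pattern_t_strength,
                   pattern_p_strength = pattern_p_strength)
    pat <- local_patterns(pc, sc)
    pert <- apply_scenario(pc, sc, pat)
    proj <- project_stems(models, inv, pc, pert)
    key <- sprintf("dt%+g_dp%+g", sc$dt, sc$dp_pct)
    guards[[key]] <- climate_space_guard(inv, pert, obs_max)

    rows <- list()
    for (sp in unique(proj$species)) {
      b <- baseline[baseline$species == sp, ]
      s <- proj[proj$species == sp, ]
      m <- merge(b[c("plot_id", "x_km", "y_km", "growth")],
                 s[c("plot_id", "growth")], by = "plot_id",
                 suffixes = c("_base", "_scen"))
      pg <- aggregate_polygons(
        data.frame(x_km = m$x_km, y_km = m$y_km,
                   baseline = m$growth_base, scenario = m$growth_scen),
        c("baseline", "scenario"), grid_km = grid_km)
      zs <- zone_summary(pg)
      rows[[sp]] <- data.frame(
        dt = sc$dt, dp_pct = sc$dp_pct, species = sp,
        mean_change_pct = zs$mean_change_pct,
        se_change_pct = zs$se_change_pct,
        fraction_declining = zs$fraction_declining,
        n_polygons = zs$n_polygons)
      pg$species <- sp
      polys[[paste(key, sp)]] <- cbind(scenario_id = key, pg)
    }
    # all species combined: per-plot sums, then polygon means
    scen_all <- stats::aggregate(growth ~ plot_id + x_km + y_km, data = proj,
                                 FUN = sum)
    m <- merge(base_all, scen_all, by = c("plot_id", "x_km", "y_km"),
               suffixes = c("_base", "_scen"))
    pg <- aggregate_polygons(
      data.frame(x_km = m$x_km, y_km = m$y_km,
                 baseline = m$growth_base, scenario = m$growth_scen),
      c("baseline", "scenario"), grid_km = grid_km)
    zs <- zone_summary(pg)
    rows[["all"]] <- data.frame(
      dt = sc$dt, dp_pct = sc$dp_pct, species = "all",
      mean_change_pct = zs$mean_change_pct,
      se_change_pct = zs$se_change_pct,
      fraction_declining = zs$fraction_declining,
      n_polygons = zs$n_polygons)
    pg$species <- "all"
    polys[[paste(key, "all")]] <- cbind(scenario_id = key, pg)
    summaries[[key]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  list(summary = out, polygons = do.call(rbind, polys), guard = guards)
}
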