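# Synthetic landscape, plots, ring series and stem inventories generated
# from a known growth response surface, so that every downstream stage of
# the pipeline can be validated by parameter recovery.

#' Define a ground-truth growth response surface
#'
#' The expected BAI (cm2 yr-1) of a tree is a product of interpretable
#' terms: an overall scale, a saturating size term `size / (size + size_half)`,
#' a negative-exponential age decline, negative-exponential competition
#' terms in BA and BAL, a Gaussian bump (or linear ramp) in temperature
#' centred on the species' thermal optimum, a Gaussian (or linear, or flat)
#' moisture response, a mild slope penalty, and categorical multipliers for
#' soil, snowfall and successional-stage classes. Residual noise is applied
#' on the `log(BAI + 1)` scale, matching the growth model's Gaussian error
#' assumption.
#'
#' @param a Overall scale (cm2 yr-1 at saturation of all terms).
#' @param size_half Half-saturation DBH (cm) of the size term.
#' @param age_scale e-folding age (years) of the age decline.
#' @param ba_coef,bal_coef Competition decay coefficients (per m2 ha-1).
#' @param t_opt Thermal optimum (degC, on the T_MAX scale).
#' @param t_width Gaussian width of the temperature response (degC).
#' @param temperature_response `"gaussian"` (unimodal, default) or
#'   `"linear"` (monotone increasing over the landscape range).
#' @param cmi_opt,cmi_width Moisture optimum and width (mm).
#' @param moisture_response `"gaussian"`, `"linear"` (monotone decreasing),
#'   or `"none"`.
#' @param slope_scale e-folding slope (%) of the slope penalty.
#' @param soil_mult,snow_mult,stage_mult Named multipliers per class level;
#'   defaults of 1 give null categorical effects.
#' @param sigma_log Residual SD on the log(BAI + 1) scale.
#' @param temperature_var,moisture_var Which climate summaries drive growth
#'   (`"tmax"`/`"tmean"` and `"cmi_gs"`/`"cmi_summer"`).
#' @return An object of class `bg_truth`.
#' @export
ground_truth <- function(a = 30, size_half = 10, age_scale = 200,
                         ba_coef = 0.008, bal_coef = 0.015,
                         t_opt = 8, t_width = 3,
                         temperature_response = c("gaussian", "linear"),
                         cmi_opt = 50, cmi_width = 250,
                         moisture_response = c("gaussian", "linear", "none"),
                         slope_scale = 200,
                         soil_mult = NULL, snow_mult = NULL, stage_mult = NULL,
                         sigma_log = 0.3,
                         temperature_var = c("tmax", "tmean"),
                         moisture_var = c("cmi_gs", "cmi_summer")) {
  full <- function(x, levels) {
    out <- stats::setNames(rep(1, length(levels)), levels)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  structure(list(
    a = a, size_half = size_half, age_scale = age_scale,
    ba_coef = ba_coef, bal_coef = bal_coef,
    t_opt = t_opt, t_width = t_width,
    temperature_response = match.arg(temperature_response),
    cmi_opt = cmi_opt, cmi_width = cmi_width,
    moisture_response = match.arg(moisture_response),
    slope_scale = slope_scale,
    soil_mult = full(soil_mult, bg_soil_classes()),
    snow_mult = full(snow_mult, bg_snow_classes()),
    stage_mult = full(stage_mult, bg_stages()),
    sigma_log = sigma_log,
    temperature_var = match.arg(temperature_var),
    moisture_var = match.arg(moisture_var)
  ), class = "bg_truth")
}

#' Evaluate a ground-truth surface
#'
#' @param truth A [ground_truth()] object.
#' @param covars Data.frame with columns `size`, `age`, `ba`, `bal`,
#'   `slope`, `soil`, `snow`, `stage` and the climate columns named by the
#'   truth's drivers (`tmax`/`tmean`, `cmi_gs`/`cmi_summer`).
#' @return Expected BAI (cm2 yr-1), strictly positive.
#' @export
eval_truth <- function(truth, covars) {
  stopifnot(inherits(truth, "bg_truth"))
  tv <- covars[[truth$temperature_var]]
  mv <- covars[[truth$moisture_var]]
  if (is.null(tv) || is.null(mv)) {
    stopf("eval_truth: covariates must include %s and %s",
          truth$temperature_var, truth$moisture_var)
  }
  tterm <- switch(truth$temperature_response,
    gaussian = exp(-(tv - truth$t_opt)^2 / (2 * truth$t_width^2)),
    linear   = 0.25 + 0.06 * pmax(tv, 0))
  mterm <- switch(truth$moisture_response,
    gaussian = exp(-(mv - truth$cmi_opt)^2 / (2 * truth$cmi_width^2)),
    linear   = exp(-5e-4 * mv),
    none     = rep(1, length(mv)))
  g <- truth$a *
    (covars$size / (covars$size + truth$size_half)) *
    exp(-covars$age / truth$age_scale) *
    exp(-truth$ba_coef * covars$ba) *
    exp(-truth$bal_coef * covars$bal) *
    tterm * mterm *
    exp(-covars$slope / truth$slope_scale) *
    truth$soil_mult[as.character(covars$soil)] *
    truth$snow_mult[as.character(covars$snow)] *
    truth$stage_mult[as.character(covars$stage)]
  unname(pmax(g, 1e-6))
}

#' Generate a synthetic study landscape
#'
#' Builds a planar grid of cells with monthly climate normals shaped like
#' the study region: mean annual temperature follows a latitudinal gradient
#' spanning roughly -4.7 to 6.7 degC, annual precipitation a longitudinal
#' gradient spanning roughly 700 to 1600 mm, with a seasonal temperature
#' cycle, summer-weighted precipitation, winter snowfall, solar radiation
#' and dewpoint consistent with a cold continental climate. The
#' growing-season share of precipitation increases slightly with the
#' latitude-like axis so that the moisture (CMI) and temperature axes of
#' the landscape are close to orthogonal, as in the study region.
#'
#' @param n_cells_x,n_cells_y Grid dimensions (longitude-like and
#'   latitude-like axes), both >= 2.
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @param cell_km Cell edge length in km (planar grid; default 10).
#' @param t_range Annual mean temperature endpoints (north, south), degC.
#' @param p_range Annual precipitation endpoints (west, east), mm.
#' @param lat_range Latitude in degrees mapped onto the latitude-like axis.
#' @param boreal_lat_frac Latitude-like fraction above which cells belong to
#'   the boreal (vs. temperate) zone.
#' @return A list of class `bg_landscape` with elements `cells` (data.frame)
#'   and `monthly` (data.frame of 12 rows per cell), plus the generation
#'   parameters.
#' @export
generate_landscape <- function(n_cells_x, n_cells_y, seed, cell_km = 10,
                               t_range = c(-4.7, 6.7),
                               p_range = c(700, 1600),
                               lat_range = c(45, 53),
                               boreal_lat_frac = 0.5) {
  if (n_cells_x < 2 || n_cells_y < 2) {
    stopf("generate_landscape: grid dimensions must be >= 2 (got %s x %s)",
          n_cells_x, n_cells_y)
  }
  set.seed(seed)
  grid <- expand.grid(ix = seq_len(n_cells_x), iy = seq_len(n_cells_y))
  lat_frac <- (grid$iy - 1) / (n_cells_y - 1)
  lon_frac <- (grid$ix - 1) / (n_cells_x - 1)
  n <- nrow(grid)
  cells <- data.frame(
    cell_id = seq_len(n),
    ix = grid$ix, iy = grid$iy,
    x_km = (grid$ix - 0.5) * cell_km,
    y_km = (grid$iy - 0.5) * cell_km,
    lat_frac = lat_frac, lon_frac = lon_frac,
    lat_deg = lat_range[1] + diff(lat_range) * lat_frac,
    altitude = 250 + 150 * lat_frac + stats::rnorm(n, 0, 20),
    t_mean_ann = t_range[2] - diff(range(t_range)) * lat_frac +
      stats::rnorm(n, 0, 0.1),
    prec_ann = p_range[1] + diff(p_range) * lon_frac + stats::rnorm(n, 0, 15),
    zone = ifelse(lat_frac >= boreal_lat_frac, "boreal", "temperate")
  )
  cells$prec_ann <- pmax(cells$prec_ann, 50)
  # per-cell continentality (diurnal half-range) and shoulder-season
  # precipitation share: independent fields that keep T_MAX distinct from
  # T_MEAN and growing-season CMI distinct from summer CMI
  cells$diurnal <- pmin(7.5, pmax(3.5, 5.5 + stats::rnorm(n, 0, 0.8)))
  cells$shoulder <- pmin(1.5, pmax(0.5, 1 + stats::rnorm(n, 0, 0.25)))

  # monthly disaggregation: July-peaking seasonal cycle, fixed diurnal
  # half-range, summer-weighted precipitation, snow below freezing
  w_prec <- c(0.050, 0.045, 0.045, 0.060, 0.090, 0.110,
              0.115, 0.110, 0.100, 0.100, 0.090, 0.085)
  gs <- 5:9
  amp <- 16
  monthly <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- 1:12
    tm <- cells$t_mean_ann[i] + amp * cos(2 * pi * (m - 7) / 12)
    half_diurnal <- cells$diurnal[i]
    w <- w_prec
    # GS precipitation share declines northward so that the PET gradient is
    # offset and CMI is nearly orthogonal to temperature, as in the region
    w[gs] <- w[gs] * (1 - 0.5 * cells$lat_frac[i])
    # shoulder months (May, September) vs core summer share varies by cell
    w[c(5, 9)] <- w[c(5, 9)] * cells$shoulder[i]
    w <- w / sum(w)
    prec <- cells$prec_ann[i] * w
    snow_frac <- pmin(1, pmax(0, (2 - tm) / 4))
    data.frame(
      cell_id = cells$cell_id[i], month = m,
      tmax = tm + half_diurnal, tmin = tm - half_diurnal,
      prec = prec, snow = prec * snow_frac,
      srad = pmax(1, 13 - 2 * cells$lat_frac[i] +
                    8 * cos(2 * pi * (m - 6.5) / 12)),
      tdew = tm - half_diurnal - 0.5,
      altitude = cells$altitude[i], lat_deg = cells$lat_deg[i]
    )
  }))
  rownames(monthly) <- NULL
  structure(list(cells = cells, monthly = monthly, cell_km = cell_km,
                 seed = seed, boreal_lat_frac = boreal_lat_frac),
            class = "bg_landscape")
}

#' Annual climate summaries for every landscape cell
#'
#' Runs [summarize_climate()] on each cell's monthly normals.
#'
#' @param landscape A [generate_landscape()] object.
#' @return Data.frame keyed by `cell_id` with the summary columns.
#' @export
landscape_climate <- function(landscape) {
  stopifnot(inherits(landscape, "bg_landscape"))
  out <- do.call(rbind, lapply(split(landscape$monthly,
                                     landscape$monthly$cell_id),
                               summarize_climate))
  out$cell_id <- as.integer(rownames(out))
  rownames(out) <- NULL
  out[order(out$cell_id), ]
}

# default per-stem species mix for synthetic stands
.SPECIES_PROBS <- c(black_spruce = 0.45, balsam_fir = 0.30,
                    jack_pine = 0.15, white_birch = 0.10)

#' Generate circular sample plots on a landscape
#'
#' Assigns each plot to a landscape cell (uniformly, with a small in-cell
#' coordinate jitter) and draws site attributes from configurable
#' marginals: slope class (converted to percent by its lower bound), soil
#' class, mean stand age (hence successional stage), and an individual stem
#' table for the nested 40/400/625 m2 subplots whose per-hectare basal area
#' is calibrated to a median near the inventory's typical 26 m2 ha-1.
#'
#' @param landscape A [generate_landscape()] object.
#' @param n_plots Number of plots, >= 1.
#' @param seed Integer seed.
#' @param species_probs Named per-stem species probabilities.
#' @param slope_probs Probabilities over the six slope classes.
#' @param soil_probs Named probabilities over [bg_soil_classes()].
#' @param stand_age_meanlog,stand_age_sdlog Log-normal stand-age parameters.
#' @param lambda_main,lambda_sapling,lambda_large Mean stem counts per
#'   subplot.
#' @return List of class `bg_plots` with `plots` (one row per plot) and
#'   `stems` (individual stem records: `plot_id`, `species`, `dbh`,
#'   `count`, `subplot`).
#' @export
generate_plots <- function(landscape, n_plots, seed,
                           species_probs = .SPECIES_PROBS,
                           slope_probs = c(0.28, 0.20, 0.32, 0.12, 0.05, 0.03),
                           soil_probs = c(mesic_medium = 0.45,
                                          mesic_coarse = 0.12,
                                          mesic_fine = 0.08,
                                          hygric_coarse = 0.05,
                                          hygric_medium = 0.12,
                                          hygric_fine = 0.06,
                                          shallow_hydric = 0.12),
                           stand_age_meanlog = log(55),
                           stand_age_sdlog = 0.45,
                           lambda_main = 42, lambda_sapling = 6,
                           lambda_large = 1.2) {
  stopifnot(inherits(landscape, "bg_landscape"))
  if (n_plots < 1) stopf("generate_plots: n_plots must be >= 1")
  if (nrow(landscape$cells) == 0L) stopf("generate_plots: empty landscape")
  set.seed(seed)
  cells <- landscape$cells
  idx <- sample.int(nrow(cells), n_plots, replace = TRUE)
  slope_cls <- sample(names(.SLOPE_CLASSES), n_plots, replace = TRUE,
                      prob = slope_probs)
  plots <- data.frame(
    plot_id = sprintf("P%05d", seq_len(n_plots)),
    cell_id = cells$cell_id[idx],
    x_km = cells$x_km[idx] +
      stats::runif(n_plots, -0.45, 0.45) * landscape$cell_km,
    y_km = cells$y_km[idx] +
      stats::runif(n_plots, -0.45, 0.45) * landscape$cell_km,
    zone = cells$zone[idx],
    slope_pct = slope_class_to_percent(slope_cls),
    soil = sample(names(soil_probs), n_plots, replace = TRUE,
                  prob = soil_probs),
    stand_age = pmax(5, stats::rlnorm(n_plots, stand_age_meanlog,
                                      stand_age_sdlog)),
    stringsAsFactors = FALSE
  )
  stems <- do.call(rbind, lapply(seq_len(n_plots), function(i) {
    n_main <- stats::rpois(1, lambda_main)
    n_sap  <- stats::rpois(1, lambda_sapling)
    n_lrg  <- stats::rpois(1, lambda_large)
    dbh <- c(pmin(31, 9 + stats::rgamma(n_main, shape = 1.8, scale = 4)),
             stats::runif(n_sap, 1, 9),
             31 + stats::rexp(n_lrg, rate = 1 / 4))
    k <- length(dbh)
    if (k == 0L) return(NULL)
    data.frame(
      plot_id = plots$plot_id[i],
      species = sample(names(species_probs), k, replace = TRUE,
                       prob = species_probs),
      dbh = dbh, count = 1L,
      subplot = subplot_for_dbh(dbh),
      stringsAsFactors = FALSE
    )
  }))
  rownames(stems) <- NULL
  structure(list(plots = plots, stems = stems), class = "bg_plots")
}

#' Assemble per-plot model covariates from a landscape
#'
#' Joins each plot with its cell's annual climate summary and derives the
#' categorical descriptors, producing the `plot_covariates` table used by
#' [prepare_tree_observations()] and the projection engine.
#'
#' @param landscape A [generate_landscape()] object.
#' @param plots The `plots` data.frame of a [generate_plots()] result.
#' @return Data.frame of plot covariates.
#' @export
plot_covariates_from_landscape <- function(landscape, plots) {
  clim <- landscape_climate(landscape)
  idx <- match(plots$cell_id, clim$cell_id)
  out <- cbind(plots, clim[idx, setdiff(names(clim), "cell_id")])
  out$stage <- as.character(classify_stage(out$stand_age))
  out$snow_class <- as.character(classify_snow(out$snow_jfm))
  rownames(out) <- NULL
  out
}

#' Generate dated ring series for cored trees of one plot
#'
#' Selects `n_trees` cored trees (DBH > 9 cm) from the plot's stem table
#' and back-computes ring widths so that each window-year BAI equals the
#' ground-truth expectation times a log-normal noise term:
#' `log(BAI + 1) = log(g + 1) + eps`, `eps ~ N(0, sigma^2)`. Radii are
#' peeled from the measured DBH inward; pre-window years share the
#' remaining radius equally so the pith is reached exactly at the tree's
#' age. An optional contamination rate multiplies a window year's BAI to
#' create outliers for screening tests. The DBH of a selected stem is
#' enlarged when needed so the peeled radii stay positive (the truth's
#' saturating size term keeps this stable).
#'
#' @param plot One row of a plot-covariates data.frame (see
#'   [plot_covariates_from_landscape()]), including `tmax`, `tmean`,
#'   `cmi_gs`, `cmi_summer`, `slope_pct`, `soil`, `snow_jfm`, `stand_age`.
#' @param stems Stem records of that plot.
#' @param truth A [ground_truth()] object.
#' @param n_trees Trees to core, 3-9 per the sampling protocol.
#' @param seed Integer seed.
#' @param sigma Log-scale residual SD; defaults to the truth's `sigma_log`.
#' @param contamination Per-ring probability of an injected outlier.
#' @param outlier_factor Multiplier applied to contaminated BAI values.
#' @param sampling_years Range of candidate coring years.
#' @param protocol `"reject"` (default) or `"warn"` when `n_trees` is
#'   outside 3-9.
#' @return List with `series` (list of [ring_series()]) and `truth_table`
#'   (data.frame of the per-tree expected BAI and generating covariates).
#' @export
generate_ring_series <- function(plot, stems, truth, n_trees, seed,
                                 sigma = NULL, contamination = 0,
                                 outlier_factor = 6,
                                 sampling_years = c(2000L, 2008L),
                                 protocol = c("reject", "warn")) {
  protocol <- match.arg(protocol)
  if (n_trees < 3 || n_trees > 9) {
    msg <- sprintf("n_trees = %d outside the 3-9 coring protocol", n_trees)
    if (protocol == "reject") stopf("generate_ring_series: %s", msg)
    warnf("generate_ring_series: %s", msg)
  }
  if (n_trees < 1) stopf("generate_ring_series: n_trees must be >= 1")
  set.seed(seed)
  sigma <- sigma %||% truth$sigma_log
  eligible <- which(stems$dbh > 9)
  if (length(eligible) == 0L) {
    stopf("generate_ring_series: plot %s has no stem above 9 cm DBH",
          plot$plot_id)
  }
  pick <- sample(eligible, n_trees, replace = length(eligible) < n_trees)
  ba <- compute_ba(stems)
  plot_snow <- classify_snow(plot$snow_jfm)
  plot_stage <- classify_stage(plot$stand_age)

  series <- vector("list", n_trees)
  truth_rows <- vector("list", n_trees)
  for (j in seq_len(n_trees)) {
    dbh <- stems$dbh[pick[j]]
    species <- stems$species[pick[j]]
    samp_year <- sample(seq(sampling_years[1], sampling_years[2]), 1)
    age <- max(30L, round(plot$stand_age + stats::rnorm(1, 0, 8)))
    outer_year <- samp_year
    pith_year <- outer_year - age + 1L
    win <- growth_window(pith_year:outer_year)
    # window-mean ring age, known a priori
    mean_age <- mean(win$years - pith_year + 1)
    bal <- compute_bal(stems, dbh)

    covars <- data.frame(size = dbh, age = mean_age, ba = ba, bal = bal,
                         tmax = plot$tmax, tmean = plot$tmean,
                         cmi_gs = plot$cmi_gs, cmi_summer = plot$cmi_summer,
                         slope = plot$slope_pct,
                         soil = plot$soil, snow = as.character(plot_snow),
                         stage = as.character(plot_stage),
                         stringsAsFactors = FALSE)
    g <- eval_truth(truth, covars)

    # post-window years (between the study period and coring) grow too
    years_desc <- outer_year:pith_year
    n_total <- length(years_desc)
    noisy_years <- years_desc[years_desc >= min(win$years)]
    eps <- stats::rnorm(length(noisy_years), 0, sigma)
    bai_noisy <- pmax(0, (g + 1) * exp(eps) - 1)
    if (contamination > 0) {
      hit <- stats::runif(length(noisy_years)) < contamination
      bai_noisy[hit] <- bai_noisy[hit] * outlier_factor
    }
    need <- sum(bai_noisy)
    # enlarge DBH if the peel would exhaust the disc; re-evaluate the truth
    # at the enlarged size (saturating size term -> converges immediately)
    if (pi * (dbh / 2)^2 < 1.4 * need) {
      dbh <- 2 * sqrt(1.4 * need / pi)
      covars$size <- dbh
      g <- eval_truth(truth, covars)
      bai_noisy <- pmax(0, (g + 1) * exp(eps) - 1)
      if (contamination > 0) bai_noisy[hit] <- bai_noisy[hit] * outlier_factor
      need <- sum(bai_noisy)
    }
    r_outer <- dbh / 2
    # peel noisy years outside-in
    r <- r_outer
    widths_desc <- numeric(n_total)
    for (i in seq_along(noisy_years)) {
      r_in <- sqrt(max(0, r^2 - bai_noisy[i] / pi))
      widths_desc[i] <- r - r_in
      r <- r_in
    }
    n_pre <- n_total - length(noisy_years)
    if (n_pre > 0) widths_desc[(length(noisy_years) + 1):n_total] <- r / n_pre
    years_asc <- rev(years_desc)
    widths_asc <- rev(widths_desc) * 10  # cm -> mm
    tree_id <- sprintf("%s_T%02d", plot$plot_id, j)
    series[[j]] <- ring_series(tree_id, plot$plot_id, species, dbh,
                               samp_year, years_asc, widths_asc)
    truth_rows[[j]] <- cbind(data.frame(tree_id = tree_id,
                                        plot_id = plot$plot_id,
                                        species = species, true_bai = g,
                                        stringsAsFactors = FALSE),
                             covars)
  }
  list(series = series, truth_table = do.call(rbind, truth_rows))
}

#' Bin plot stem tables into a 2-cm DBH-class inventory
#'
#' Stems above 9 cm DBH are classified into even 2-cm classes per species
#' using half-open, left-closed bins `[9, 11), [11, 13), ...`; each record
#' carries the class midpoint, the summed count and the per-hectare
#' expansion factor of its source subplot.
#'
#' @param stems Stem records (`plot_id`, `species`, `dbh`, `count`,
#'   `subplot`).
#' @return Data.frame with `plot_id`, `species`, `dbh_class` (midpoint),
#'   `count`, `subplot`, `expansion`.
#' @export
generate_stem_inventory <- function(stems) {
  if (is.null(stems) || nrow(stems) == 0L) {
    stopf("generate_stem_inventory: empty stem table")
  }
  assert_cols(stems, c("plot_id", "species", "dbh", "count", "subplot"),
              "stem table")
  st <- stems[stems$dbh >= 9, , drop = FALSE]
  st$dbh_class <- 9 + 2 * floor((st$dbh - 9) / 2) + 1  # [9,11) -> 10, ...
  agg <- stats::aggregate(count ~ plot_id + species + dbh_class + subplot,
                          data = st, FUN = sum)
  agg$expansion <- unname(expansion_factor(agg$subplot))
  agg[order(agg$plot_id, agg$species, agg$dbh_class), ]
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_landscape()], [generate_plots()],
#' [plot_covariates_from_landscape()] and [generate_ring_series()] over all
#' plots, plus the 2-cm class stem inventory. Seeds for each stage are
#' derived deterministically from `seed`.
#'
#' @param seed Master integer seed.
#' @param n_cells_x,n_cells_y,cell_km Landscape dimensions.
#' @param n_plots Number of plots.
#' @param trees_per_plot Cored trees per plot (3-9).
#' @param truth A [ground_truth()]; defaults to `ground_truth()`.
#' @param sigma,contamination Passed to [generate_ring_series()].
#' @param ... Further arguments to [generate_plots()].
#' @return List with `landscape`, `plots`, `stems`, `plot_covariates`,
#'   `series` (flat list over all plots), `truth_table`, `inventory`,
#'   `truth`.
#' @export
simulate_dataset <- function(seed, n_cells_x = 12, n_cells_y = 12,
                             cell_km = 10, n_plots = 150,
                             trees_per_plot = 4, truth = ground_truth(),
                             sigma = NULL, contamination = 0, ...) {
  land <- generate_landscape(n_cells_x, n_cells_y, seed = seed,
                             cell_km = cell_km)
  pl <- generate_plots(land, n_plots, seed = seed + 1L, ...)
  cov <- plot_covariates_from_landscape(land, pl$plots)
  all_series <- list(); truth_tabs <- vector("list", nrow(cov))
  for (i in seq_len(nrow(cov))) {
    st <- pl$stems[pl$stems$plot_id == cov$plot_id[i], , drop = FALSE]
    if (!any(st$dbh > 9)) next
    rs <- generate_ring_series(cov[i, ], st, truth, trees_per_plot,
                               seed = seed + 1L + i, sigma = sigma,
                               contamination = contamination)
    all_series <- c(all_series, rs$series)
    truth_tabs[[i]] <- rs$truth_table
  }
  list(landscape = land, plots = pl$plots, stems = pl$stems,
       plot_covariates = cov, series = all_series,
       truth_table = do.call(rbind, truth_tabs),
       inventory = generate_stem_inventory(pl$stems),
       truth = truth)
}
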