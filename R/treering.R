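# Ring-width series -> annual basal area increment (BAI), outlier
# screening, growth-window selection and model-ready tree summaries.

#' Construct a ring-width series
#'
#' One cored tree's dated ring widths together with its measured DBH and
#' sampling year. Years must be contiguous from pith to the outermost ring;
#' the outermost ring corresponds to the sampling year, or to the year
#' before when the core was taken prior to the start of ring formation
#' (`outer_lag = 1`).
#'
#' @param tree_id,plot_id Identifiers.
#' @param species Species code (see [bg_species()]).
#' @param dbh_cm DBH at sampling, cm (> 9 per the coring protocol).
#' @param sampling_year Calendar year the tree was cored.
#' @param years Integer vector of ring calendar years (contiguous).
#' @param width_mm Ring widths, mm, same length as `years`, non-negative.
#' @param outer_lag 0 if the outermost ring is the sampling year, 1 if it is
#'   the year before.
#' @return An object of class `ring_series`.
#' @export
ring_series <- function(tree_id, plot_id, species, dbh_cm, sampling_year,
                        years, width_mm, outer_lag = 0L) {
  years <- as.integer(years)
  o <- order(years)
  years <- years[o]; width_mm <- width_mm[o]
  if (length(years) != length(width_mm)) {
    stopf("ring_series %s: years and widths differ in length", tree_id)
  }
  if (length(years) > 1L && !all(diff(years) == 1L)) {
    stopf("ring_series %s: ring years not contiguous (incomplete core?)",
          tree_id)
  }
  if (any(width_mm < 0)) stopf("ring_series %s: negative ring width", tree_id)
  outer <- years[length(years)]
  if (outer != sampling_year - outer_lag) {
    stopf("ring_series %s: outermost ring %d does not match sampling year %d (lag %d)",
          tree_id, outer, sampling_year, outer_lag)
  }
  structure(
    list(tree_id = tree_id, plot_id = plot_id, species = species,
         dbh_cm = dbh_cm, sampling_year = as.integer(sampling_year),
         years = years, width_mm = width_mm, outer_lag = as.integer(outer_lag)),
    class = "ring_series")
}

#' Convert a ring-width series to annual basal area increments
#'
#' Radii are reconstructed from the bark inward, using the measured DBH as
#' the outer value: the radius at the end of the outermost ring year is
#' DBH/2 and each earlier radius is obtained by subtracting that year's
#' ring width. The BAI of year t is the annulus area
#' `pi * (r_t^2 - r_{t-1}^2)` in cm2.
#'
#' @param series A [ring_series()].
#' @return Data.frame with one row per ring year: `year`, `width_mm`,
#'   `radius_cm` (radius at the end of the year), `dbh_cm` (reconstructed
#'   diameter at the end of the year), `bai` (cm2 yr-1), `age` (rings
#'   counted from the pith up to and including the year).
#' @export
rings_to_bai <- function(series) {
  stopifnot(inherits(series, "ring_series"))
  n <- length(series$years)
  w_cm <- series$width_mm / 10
  # outer radius after each year's growth, reconstructed outside-in
  r_end <- series$dbh_cm / 2 - rev(c(0, cumsum(rev(w_cm))[-n]))
  r_start <- r_end - w_cm
  if (r_start[1] < -1e-9) {
    stopf("rings_to_bai: tree %s: cumulative ring widths exceed DBH/2 (pith radius %.3f cm)",
          series$tree_id, r_start[1])
  }
  r_start[1] <- max(r_start[1], 0)
  data.frame(
    year = series$years,
    width_mm = series$width_mm,
    radius_cm = r_end,
    dbh_cm = 2 * r_end,
    bai = pi * (r_end^2 - r_start^2),
    age = seq_len(n)
  )
}

#' Tukey outlier screen
#'
#' Flags values outside the fences `[Q1 - k * IQR, Q3 + k * IQR]`, with
#' quartiles computed by linear interpolation of order statistics
#' (`stats::quantile` type 7). With fewer than 4 values no screening is
#' performed (all values kept, with a warning).
#'
#' @param values Numeric vector (a tree's annual growth values).
#' @param k Fence constant; default 3.
#' @return Logical vector, `TRUE` where the value is flagged as an outlier.
#' @export
tukey_screen <- function(values, k = 3) {
  if (length(values) < 4L) {
    warnf("tukey_screen: fewer than 4 values; no screening applied")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (is.infinite(k)) return(rep(FALSE, length(values)))
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Select a tree's growth window
#'
#' Growth is averaged over the most recent (at most) 15 calendar years of
#' ring formation that fall within the study period. Trees with fewer than
#' `min_years` eligible years are marked as dropped (e.g. a tree sampled in
#' 1997 retains the 13 years 1985-1997; a tree with rings only from 2000
#' onward retains 6 years within 1985-2005 and is dropped).
#'
#' @param years Integer vector of ring calendar years available for a tree.
#' @param period Two-element inclusive calendar bounds, default `c(1985, 2005)`.
#' @param max_years Window cap, default 15.
#' @param min_years Minimum years required to keep the tree, default 10.
#' @return List with `years` (selected calendar years, ascending), `n`, and
#'   `kept` (logical).
#' @export
growth_window <- function(years, period = c(1985L, 2005L),
                          max_years = 15L, min_years = 10L) {
  eligible <- sort(unique(as.integer(years)))
  eligible <- eligible[eligible >= period[1] & eligible <= period[2]]
  sel <- utils::tail(eligible, max_years)
  list(years = sel, n = length(sel), kept = length(sel) >= min_years)
}

#' Summarise a ring series into model-ready tree fields
#'
#' Applies [growth_window()] and the Tukey screen (within the window, by
#' default) to a tree's BAI series, then averages BAI, reconstructed annual
#' diameter and ring-count age over the (unflagged) window years.
#'
#' @param series A [ring_series()].
#' @param k Tukey fence constant; `Inf` disables screening.
#' @param screen `"window"` (default) screens annual BAI within the growth
#'   window; `"series"` screens over the full series before windowing.
#' @param period,max_years,min_years Passed to [growth_window()].
#' @return A one-row data.frame with `tree_id`, `plot_id`, `species`,
#'   `bai` (mean, cm2 yr-1), `size` (mean annual DBH, cm), `age` (mean ring
#'   age, years), `n_years`, `n_flagged`, `dbh_cm`, `sampling_year`; or
#'   `NULL` (with a message) when the tree is dropped.
#' @export
summarize_tree <- function(series, k = 3, screen = c("window", "series"),
                           period = c(1985L, 2005L), max_years = 15L,
                           min_years = 10L) {
  screen <- match.arg(screen)
  tab <- rings_to_bai(series)
  win <- growth_window(tab$year, period = period, max_years = max_years,
                       min_years = min_years)
  if (!win$kept) {
    message(sprintf("tree %s dropped: only %d year(s) in window",
                    series$tree_id, win$n))
    return(NULL)
  }
  in_win <- tab$year %in% win$years
  if (screen == "series") {
    flags_all <- tukey_screen(tab$bai, k = k)
    flags <- flags_all[in_win]
  } else {
    flags <- tukey_screen(tab$bai[in_win], k = k)
  }
  wt <- tab[in_win, , drop = FALSE]
  use <- !flags
  if (!any(use)) {
    message(sprintf("tree %s dropped: all window years flagged as outliers",
                    series$tree_id))
    return(NULL)
  }
  data.frame(
    tree_id = series$tree_id,
    plot_id = series$plot_id,
    species = series$species,
    bai = mean(wt$bai[use]),
    size = mean(wt$dbh_cm),
    age = mean(wt$age),
    n_years = nrow(wt),
    n_flagged = sum(flags),
    dbh_cm = series$dbh_cm,
    sampling_year = series$sampling_year,
    stringsAsFactors = FALSE
  )
}

#' Prepare model-ready tree observations
#'
#' Runs [summarize_tree()] over a collection of ring series and joins each
#' surviving tree with its plot covariates and competition indices. BAL is
#' computed against the plot stem table using the tree's measured DBH at
#' sampling (competition is assessed at the time of stand sampling).
#'
#' @param series_list List of [ring_series()] objects.
#' @param plot_covariates Data.frame with one row per plot: `plot_id`,
#'   `slope_pct`, `soil`, `snow_jfm`, `stand_age`, `tmax`, `tmean`,
#'   `cmi_gs`, `cmi_summer`, `prec_gs`, plus any extra columns (carried
#'   through).
#' @param stems Data.frame of stem records with `plot_id`, `dbh`, `count`,
#'   `subplot`.
#' @param ... Passed to [summarize_tree()].
#' @return List with `observations` (data.frame, one row per kept tree,
#'   including factors `soil`, `snow`, `stage`) and `dropped` (data.frame
#'   tallying trees dropped per reason).
#' @export
prepare_tree_observations <- function(series_list, plot_covariates, stems, ...) {
  assert_cols(plot_covariates,
              c("plot_id", "slope_pct", "soil", "snow_jfm", "stand_age",
                "tmax", "tmean", "cmi_gs", "cmi_summer", "prec_gs"),
              "plot covariates")
  rows <- vector("list", length(series_list))
  n_drop <- 0L
  for (i in seq_along(series_list)) {
    rows[[i]] <- withCallingHandlers(
      summarize_tree(series_list[[i]], ...),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(rows[[i]])) n_drop <- n_drop + 1L
  }
  obs <- do.call(rbind, rows)
  if (is.null(obs) || nrow(obs) == 0L) {
    stopf("prepare_tree_observations: no tree survived filtering")
  }
  idx <- match(obs$plot_id, plot_covariates$plot_id)
  if (anyNA(idx)) {
    stopf("prepare_tree_observations: plot covariates missing for plot(s): %s",
          paste(unique(obs$plot_id[is.na(idx)]), collapse = ", "))
  }
  pc <- plot_covariates[idx, , drop = FALSE]
  obs <- cbind(obs, pc[setdiff(names(pc), "plot_id")])
  stems_by_plot <- split(stems, stems$plot_id)
  ba_by_plot <- vapply(stems_by_plot, compute_ba, numeric(1))
  obs$ba <- unname(ba_by_plot[obs$plot_id])
  obs$bal <- NA_real_
  for (p in unique(obs$plot_id)) {
    r <- obs$plot_id == p
    obs$bal[r] <- compute_bal(stems_by_plot[[p]], obs$dbh_cm[r])
  }
  obs$soil <- as_soil_class(as.character(obs$soil))
  obs$snow <- classify_snow(obs$snow_jfm)
  obs$stage <- classify_stage(obs$stand_age)
  obs$slope <- obs$slope_pct
  obs$cmi <- obs$cmi_gs
  rownames(obs) <- NULL
  list(observations = obs,
       dropped = data.frame(n_input = length(series_list),
                            n_kept = nrow(obs), n_dropped = n_drop))
}
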