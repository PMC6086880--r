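# Climate variables: FAO-56 Penman-Monteith PET, climate moisture index,
# and the annual summaries used as growth-model covariates.

# FAO-56 constants
.FAO <- list(
  gsc     = 0.0820,   # solar constant, MJ m-2 min-1
  sigma   = 4.903e-9, # Stefan-Boltzmann, MJ K-4 m-2 day-1
  albedo  = 0.23,     # reference crop albedo
  a_s     = 0.75,     # clear-sky transmissivity intercept (Rso)
  z_coef  = 2e-5      # altitude correction of clear-sky radiation
)

# saturation vapour pressure (kPa) at temperature T (degC), FAO-56 eq. 11
svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' Monthly FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Computes reference-surface potential evapotranspiration (PET) for one or
#' more months from monthly-mean daily inputs, following the FAO-56
#' formulation: saturation vapour pressure averaged between the monthly
#' daily maximum and minimum temperatures, actual vapour pressure from
#' dewpoint, atmospheric pressure from altitude, net radiation from measured
#' incoming solar radiation with a clear-sky longwave correction, and
#' extraterrestrial radiation evaluated at the mid-month day of year. Soil
#' heat flux is taken as zero at monthly resolution. The daily reference
#' evapotranspiration is multiplied by the number of days in the month.
#'
#' @param tmax,tmin Monthly mean daily maximum/minimum temperature (degC).
#' @param srad Incoming solar radiation (MJ m-2 day-1).
#' @param tdew Dewpoint temperature (degC).
#' @param lat_deg Latitude in decimal degrees.
#' @param altitude Altitude above sea level (m).
#' @param month Calendar month, 1-12.
#' @param wind Wind speed at 2 m (m s-1); defaults to the FAO-56 standard
#'   2 m s-1 since wind is not among the available station inputs.
#' @return PET in mm per month, never negative. Vectorised over all inputs.
#' @references Allen, R.G. et al. (1998) Crop evapotranspiration, FAO
#'   Irrigation and Drainage Paper 56.
#' @export
#' @examples
#' penman_monteith_pet(tmax = 24, tmin = 12, srad = 22, tdew = 10,
#'                     lat_deg = 48, altitude = 300, month = 7)
penman_monteith_pet <- function(tmax, tmin, srad, tdew, lat_deg, altitude,
                                month, wind = 2) {
  n <- max(length(tmax), length(tmin), length(srad), length(tdew),
           length(lat_deg), length(altitude), length(month), length(wind))
  tmax <- rep_len(tmax, n); tmin <- rep_len(tmin, n)
  srad <- rep_len(srad, n); tdew <- rep_len(tdew, n)
  lat_deg <- rep_len(lat_deg, n); altitude <- rep_len(altitude, n)
  month <- rep_len(as.integer(month), n); wind <- rep_len(wind, n)

  if (anyNA(c(tmax, tmin, srad, tdew, lat_deg, altitude, month))) {
    stopf("penman_monteith_pet: missing values in inputs")
  }
  if (any(tmax < tmin)) stopf("penman_monteith_pet: tmax < tmin")
  if (any(tmax > 60 | tmin < -60)) {
    stopf("penman_monteith_pet: temperatures outside [-60, 60] degC")
  }
  if (any(srad < 0)) stopf("penman_monteith_pet: negative solar radiation")
  if (any(month < 1L | month > 12L)) stopf("penman_monteith_pet: month outside 1..12")

  tmean <- (tmax + tmin) / 2

  # psychrometric constant from altitude-derived pressure (eqs. 7-8)
  pres  <- 101.3 * ((293 - 0.0065 * altitude) / 293)^5.26
  gamma <- 0.000665 * pres

  # vapour pressures (eqs. 11-14) and slope of the svp curve (eq. 13)
  es    <- (svp(tmax) + svp(tmin)) / 2
  ea    <- svp(tdew)
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2

  # extraterrestrial radiation at mid-month (eqs. 21-25)
  phi <- lat_deg * pi / 180
  j   <- mid_month_doy(month)
  dr  <- 1 + 0.033 * cos(2 * pi * j / 365)
  dec <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  x   <- pmin(1, pmax(-1, -tan(phi) * tan(dec)))
  ws  <- acos(x)
  ra  <- (24 * 60 / pi) * .FAO$gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))

  # net radiation (eqs. 37-40); relative shortwave bounded to [0.3, 1]
  rso <- (.FAO$a_s + .FAO$z_coef * altitude) * ra
  rel <- ifelse(rso > 0, pmin(1, pmax(0.3, srad / rso)), 1)
  rns <- (1 - .FAO$albedo) * srad
  rnl <- .FAO$sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rn  <- rns - rnl

  # reference ET, mm day-1 (eq. 6), soil heat flux G = 0 at monthly step
  et0 <- (0.408 * delta * rn +
            gamma * (900 / (tmean + 273)) * wind * (es - ea)) /
    (delta + gamma * (1 + 0.34 * wind))

  pmax(0, et0) * days_in_month(month)
}

#' Climate moisture index
#'
#' The balance of precipitation and potential evapotranspiration over a
#' period: `CMI = prec - pet`, in mm. Exact subtraction, no capping.
#'
#' @param prec Precipitation (mm), non-negative.
#' @param pet Potential evapotranspiration (mm).
#' @return CMI in mm (may be negative).
#' @export
cmi <- function(prec, pet) {
  if (any(prec < 0, na.rm = TRUE)) stopf("cmi: negative precipitation")
  prec - pet
}

#' Classify January-March snowfall
#'
#' @param snow_mm Total January-March snowfall (mm).
#' @return Factor with levels low (< 140), medium (140-200, bounds
#'   included), high (> 200).
#' @export
classify_snow <- function(snow_mm) {
  lab <- ifelse(snow_mm < 140, "low", ifelse(snow_mm <= 200, "medium", "high"))
  factor(lab, levels = bg_snow_classes())
}

#' Summarise one plot-year of monthly climate
#'
#' Computes the annual climate summary used by the growth model from a
#' complete 12-month record: mean annual daily maximum temperature (T_MAX),
#' mean annual daily temperature (T_MEAN), growing-season (May-September)
#' and summer (June-August) climate moisture indices, growing-season
#' precipitation, January-March snowfall, and monthly PET.
#'
#' @param monthly A data.frame with one row per month and columns `month`
#'   (1-12, each exactly once), `tmax`, `tmin`, `prec`, `snow`, `srad`,
#'   `tdew`, `altitude`, `lat_deg`.
#' @param wind Wind speed passed to [penman_monteith_pet()].
#' @return A one-row data.frame with columns `tmax`, `tmean`, `cmi_gs`,
#'   `cmi_summer`, `prec_gs`, `snow_jfm`, `pet_annual`.
#' @export
summarize_climate <- function(monthly, wind = 2) {
  assert_cols(monthly, c("month", "tmax", "tmin", "prec", "snow", "srad",
                         "tdew", "altitude", "lat_deg"), "monthly climate")
  mo <- sort(unique(as.integer(monthly$month)))
  if (!identical(mo, 1:12) || nrow(monthly) != 12L) {
    stopf("summarize_climate: incomplete year; months present: %s",
          paste(sort(monthly$month), collapse = ","))
  }
  monthly <- monthly[order(monthly$month), ]
  pet <- penman_monteith_pet(monthly$tmax, monthly$tmin, monthly$srad,
                             monthly$tdew, monthly$lat_deg, monthly$altitude,
                             monthly$month, wind = wind)
  cmi_m <- cmi(monthly$prec, pet)
  gs <- 5:9   # May-September
  su <- 6:8   # June-August
  data.frame(
    tmax       = mean(monthly$tmax),
    tmean      = mean((monthly$tmax + monthly$tmin) / 2),
    cmi_gs     = sum(cmi_m[gs]),
    cmi_summer = sum(cmi_m[su]),
    prec_gs    = sum(monthly$prec[gs]),
    snow_jfm   = sum(monthly$snow[1:3]),
    pet_annual = sum(pet)
  )
}

#' Average annual climate summaries over a tree's growth window
#'
#' Climate covariates entering the growth model are the arithmetic means of
#' the annual summaries over the years of each tree's growth window.
#'
#' @param summaries Data.frame of per-year rows as returned by
#'   [summarize_climate()], with an additional `year` column.
#' @param window Integer vector of calendar years to average over; must be a
#'   subset of `summaries$year`.
#' @return A one-row data.frame with the same summary columns.
#' @export
window_average_climate <- function(summaries, window) {
  if (length(window) == 0L) stopf("window_average_climate: empty window")
  assert_cols(summaries, "year", "climate summaries")
  miss <- setdiff(window, summaries$year)
  if (length(miss) > 0L) {
    stopf("window_average_climate: years not available: %s",
          paste(miss, collapse = ","))
  }
  sel <- summaries[summaries$year %in% window, , drop = FALSE]
  num <- setdiff(names(sel), "year")
  out <- as.data.frame(lapply(sel[num], mean))
  out
}
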