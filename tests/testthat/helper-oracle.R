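# Independent oracles used to cross-check package computations.

# Independently transcribed FAO-56 reference evapotranspiration, monthly.
# Scalar, equation-by-equation transcription from Allen et al. (1998),
# kept deliberately separate from the package implementation. Shares the
# package's stated conventions: G = 0, wind 2 m/s default, Rs/Rso bounded
# to [0.3, 1], ET0 floored at 0, mid-month day of year.
oracle_fao56_month <- function(tmax, tmin, srad, tdew, lat_deg, altitude,
                               month, wind = 2) {
  stopifnot(tmax >= tmin, srad >= 0)
  ndays <- switch(month, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  doy <- switch(month, 15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)

  e0 <- function(temp) 0.6108 * exp((17.27 * temp) / (temp + 237.3))
  tmean <- (tmax + tmin) / 2

  # eq. 7/8: pressure and psychrometric constant
  p_kpa <- 101.3 * ((293 - 0.0065 * altitude) / 293)^5.26
  psy <- 0.000665 * p_kpa
  # eq. 13: slope of saturation vapour pressure curve
  slope <- 4098 * e0(tmean) / (tmean + 237.3)^2
  # eq. 12/14
  e_s <- (e0(tmax) + e0(tmin)) / 2
  e_a <- e0(tdew)

  # eq. 21-25: extraterrestrial radiation
  lat_rad <- pi / 180 * lat_deg
  d_r <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  delta <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  arg <- -tan(lat_rad) * tan(delta)
  if (arg > 1) arg <- 1
  if (arg < -1) arg <- -1
  omega_s <- acos(arg)
  r_a <- 24 * 60 / pi * 0.0820 * d_r *
    (omega_s * sin(lat_rad) * sin(delta) +
       cos(lat_rad) * cos(delta) * sin(omega_s))

  # eq. 37-40: net radiation
  r_so <- (0.75 + 2e-05 * altitude) * r_a
  ratio <- if (r_so > 0) srad / r_so else 1
  if (ratio > 1) ratio <- 1
  if (ratio < 0.3) ratio <- 0.3
  r_ns <- 0.77 * srad
  boltz <- 4.903e-09
  r_nl <- boltz * (((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2) *
    (0.34 - 0.14 * sqrt(max(e_a, 0))) * (1.35 * ratio - 0.35)
  r_n <- r_ns - r_nl

  # eq. 6 with G = 0
  num <- 0.408 * slope * r_n +
    psy * 900 / (tmean + 273) * wind * (e_s - e_a)
  den <- slope + psy * (1 + 0.34 * wind)
  max(0, num / den) * ndays
}

# brute-force Tukey fence oracle (type-7 quartiles)
oracle_tukey_flags <- function(x, k = 3) {
  xs <- sort(x)
  n <- length(xs)
  qidx <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  q1 <- qidx(0.25); q3 <- qidx(0.75)
  x < q1 - k * (q3 - q1) | x > q3 + k * (q3 - q1)
}

# random valid PET input generator for sweeps
random_pet_inputs <- function(n, seed) {
  set.seed(seed)
  tmin <- runif(n, -30, 22)
  data.frame(
    tmax = tmin + runif(n, 0.5, 15),
    tmin = tmin,
    srad = runif(n, 1, 30),
    tdew = tmin - runif(n, 0, 4),
    lat_deg = runif(n, 42, 58),
    altitude = runif(n, 0, 1000),
    month = sample(1:12, n, replace = TRUE)
  )
}
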