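#' @keywords internal
#' @importFrom stats rnorm runif rlnorm rpois rgamma rexp quantile median
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# sprintf-style stop/warning without call noise
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Species known to the package
#'
#' Codes for the seven most common boreal tree species of Eastern Canada.
#'
#' @return Character vector of species codes.
#' @export
bg_species <- function() {
  c("black_spruce", "white_spruce", "balsam_fir", "jack_pine",
    "aspen", "white_birch", "larch")
}

#' Soil physical environment taxonomy
#'
#' Seven-level classification combining drainage and texture for mineral
#' soils (xeric-to-mesic vs. hygric crossed with coarse/medium/fine), with
#' very thin or very stony soils and hydric/organic soils merged into a
#' single seventh level. The merge of the shallow/stony and hydric
#' categories is a configuration choice; see the methods vignette.
#'
#' @return Character vector of the seven soil class labels, reference first.
#' @export
bg_soil_classes <- function() {
  c("mesic_medium", "mesic_coarse", "mesic_fine",
    "hygric_coarse", "hygric_medium", "hygric_fine",
    "shallow_hydric")
}

#' Snowfall classes
#'
#' January-March total snowfall classes: low below 140 mm, medium 140-200 mm
#' (both bounds included), high above 200 mm.
#'
#' @return Character vector of class labels.
#' @export
bg_snow_classes <- function() c("low", "medium", "high")

#' Stand successional stages
#'
#' Age-derived stand classes with breakpoints at 20, 70 and 100 years.
#'
#' @return Character vector of stage labels in age order.
#' @export
bg_stages <- function() c("early_seral", "immature", "mature", "old_growth")

# days per month, non-leap year (climate normals)
days_in_month <- function(month) {
  c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
}

# mid-month day of year, used for extraterrestrial radiation
mid_month_doy <- function(month) {
  c(15L, 46L, 74L, 105L, 135L, 166L, 196L, 227L, 258L, 288L, 319L, 349L)[month]
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}
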