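# Competition indices from nested-plot stem tables and categorical site
# descriptors (slope class, soil class, stand successional stage).

# nested circular subplot areas, m2
.SUBPLOT_AREA <- c(sapling = 40, main = 400, large = 625)

#' Per-hectare expansion factor of a nested subplot
#'
#' Stems are tallied in nested circular plots: saplings (1-9 cm DBH) in a
#' 40 m2 subplot, stems of 9-31 cm in the 400 m2 main plot, and stems above
#' 31 cm in a 625 m2 plot. The expansion factor is 10000 / area, the number
#' of stems per hectare each tallied stem represents.
#'
#' @param subplot Character vector among `"sapling"`, `"main"`, `"large"`.
#' @return Numeric multiplier(s): 250, 25 and 16 respectively.
#' @export
expansion_factor <- function(subplot) {
  bad <- setdiff(unique(subplot), names(.SUBPLOT_AREA))
  if (length(bad) > 0L) {
    stopf("expansion_factor: unknown subplot kind(s): %s",
          paste(bad, collapse = ", "))
  }
  10000 / .SUBPLOT_AREA[subplot]
}

#' Nested subplot that tallies a stem of given DBH
#'
#' Saplings (1-9 cm) are tallied in the 40 m2 subplot, stems of 9-31 cm in
#' the 400 m2 main plot and stems above 31 cm in the 625 m2 plot.
#'
#' @param dbh DBH in cm. Vectorised.
#' @return Character vector among `"sapling"`, `"main"`, `"large"`.
#' @export
subplot_for_dbh <- function(dbh) {
  ifelse(dbh > 31, "large", ifelse(dbh > 9, "main", "sapling"))
}

# basal area of one stem, m2, from DBH in cm
stem_ba_m2 <- function(dbh_cm) pi * (dbh_cm / 200)^2

#' Symmetric competition: total plot basal area per hectare
#'
#' The sum of individual basal areas of all stems with DBH > 1 cm, each
#' scaled by its subplot's per-hectare expansion factor.
#'
#' @param stems Data.frame with columns `dbh` (cm), `count`, `subplot`.
#' @return BA in m2 ha-1.
#' @export
compute_ba <- function(stems) {
  if (nrow(stems) == 0L) return(0)
  assert_cols(stems, c("dbh", "count", "subplot"), "stem table")
  keep <- stems$dbh > 1
  sum(stems$count[keep] * stem_ba_m2(stems$dbh[keep]) *
        expansion_factor(stems$subplot[keep]))
}

#' Asymmetric competition: basal area of larger trees
#'
#' Sum of per-hectare basal area of stems strictly larger in DBH than the
#' focal tree. Ties (equal DBH) do not compete asymmetrically.
#'
#' @param stems Data.frame with columns `dbh`, `count`, `subplot`.
#' @param focal_dbh Focal tree DBH (cm), > 0. Vectorised.
#' @return BAL in m2 ha-1, one value per focal DBH; always <= [compute_ba()].
#' @export
compute_bal <- function(stems, focal_dbh) {
  if (any(focal_dbh <= 0)) stopf("compute_bal: focal DBH must be positive")
  if (nrow(stems) == 0L) return(rep(0, length(focal_dbh)))
  assert_cols(stems, c("dbh", "count", "subplot"), "stem table")
  keep <- stems$dbh > 1
  st <- stems[keep, , drop = FALSE]
  contrib <- st$count * stem_ba_m2(st$dbh) * expansion_factor(st$subplot)
  vapply(focal_dbh, function(d) sum(contrib[st$dbh > d]), numeric(1))
}

# slope classes used in temporary plots, mapped to the class lower bound
.SLOPE_CLASSES <- c("0-3" = 0, "4-8" = 4, "9-16" = 9, "16-30" = 16,
                    "31-40" = 31, ">=41" = 41)

#' Convert a slope class label to a quantitative slope
#'
#' Temporary sample plots record terrain slope in classes; these are
#' converted to percent using the lower bound of each class (e.g. the
#' 9-16 % class becomes 9 %).
#'
#' @param label Character vector of class labels: `"0-3"`, `"4-8"`,
#'   `"9-16"`, `"16-30"`, `"31-40"`, `">=41"`.
#' @return Slope in percent.
#' @export
slope_class_to_percent <- function(label) {
  bad <- setdiff(unique(label), names(.SLOPE_CLASSES))
  if (length(bad) > 0L) {
    stopf("slope_class_to_percent: unknown class(es): %s",
          paste(bad, collapse = ", "))
  }
  unname(.SLOPE_CLASSES[label])
}

#' Classify stand successional stage from mean stand age
#'
#' Stages are derived from the average tree age of the stand: early-seral
#' 0-20 years, immature 20-70, mature 70-100 (100 included), old-growth
#' above 100.
#'
#' @param mean_age Mean stand age in years, >= 0. Vectorised.
#' @return Factor with levels `early_seral`, `immature`, `mature`,
#'   `old_growth`.
#' @export
classify_stage <- function(mean_age) {
  if (any(mean_age < 0)) stopf("classify_stage: negative age")
  lab <- ifelse(mean_age < 20, "early_seral",
         ifelse(mean_age < 70, "immature",
         ifelse(mean_age <= 100, "mature", "old_growth")))
  factor(lab, levels = bg_stages())
}

#' Validate a soil class label
#'
#' @param label Character vector of soil class labels.
#' @return The labels as a factor over [bg_soil_classes()].
#' @export
as_soil_class <- function(label) {
  bad <- setdiff(unique(label), bg_soil_classes())
  if (length(bad) > 0L) {
    stopf("as_soil_class: unknown soil class(es): %s (valid: %s)",
          paste(bad, collapse = ", "),
          paste(bg_soil_classes(), collapse = ", "))
  }
  factor(label, levels = bg_soil_classes())
}
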