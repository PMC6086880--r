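# The species growth model: a penalized additive model on log(BAI + 1)
# with parametric size terms, bounded smooths, a temperature-moisture
# tensor interaction, factor-modified smooths for soil / snow / stage,
# and a Duan smearing back-transform.

#' Specify the growth model
#'
#' The response is `log(BAI + 1)` with Gaussian errors. Parametric terms:
#' intercept, `log(Size)` and `Size` (growth increases roughly
#' exponentially with size). Smooth terms: cubic regression splines in age,
#' BAL, BA, slope, temperature and CMI, each with basis dimension bounded
#' to `basis_dim`; a scale-invariant tensor-product interaction of
#' temperature and CMI bounded to `tensor_dim` per margin. Categorical
#' modifiers enter as parametric intercept offsets plus difference smooths
#' (ordered-factor `by=` smooths): soil modifies the temperature and CMI
#' smooths, snowfall class the CMI smooth, and successional stage the
#' temperature, CMI, BA and BAL smooths.
#'
#' @param basis_dim Basis dimension bound of univariate smooths (default 4).
#' @param tensor_dim Per-margin basis bound of the tensor interaction
#'   (default 3).
#' @param factor_smooths Include the factor-by difference smooths (default
#'   `TRUE`); `FALSE` retains only the intercept offsets, for lean fits.
#' @param temperature_var,moisture_var Climate covariates to use
#'   (`"tmax"`/`"tmean"`, `"cmi_gs"`/`"cmi_summer"`).
#' @param method Smoothness-selection criterion, default `"REML"`.
#' @param engine `"auto"` (exact REML gam below `bam_threshold` rows, bam
#'   with discrete covariates above), `"gam"`, or `"bam"`. The discrete bam
#'   approximation trades some smoothness-selection accuracy for speed and
#'   is reserved for datasets too large for the exact fit.
#' @param bam_threshold Row count above which `"auto"` switches to bam.
#' @param smear_by Optional factor column name for stratified smearing
#'   factors; `NULL` (default) uses a single global factor.
#' @return An object of class `bg_model_spec`.
#' @export
model_spec <- function(basis_dim = 4, tensor_dim = 3, factor_smooths = TRUE,
                       temperature_var = c("tmax", "tmean"),
                       moisture_var = c("cmi_gs", "cmi_summer"),
                       method = "REML", engine = c("auto", "gam", "bam"),
                       bam_threshold = 10000, smear_by = NULL) {
  structure(list(
    basis_dim = basis_dim, tensor_dim = tensor_dim,
    factor_smooths = factor_smooths,
    temperature_var = match.arg(temperature_var),
    moisture_var = match.arg(moisture_var),
    method = method, engine = match.arg(engine),
    bam_threshold = bam_threshold, smear_by = smear_by
  ), class = "bg_model_spec")
}

# prepare the model frame: map climate drivers onto generic columns,
# coerce factors, drop unusable levels
model_frame <- function(data, spec) {
  assert_cols(data, c("bai", "size", "age", "ba", "bal", "slope",
                      spec$temperature_var, spec$moisture_var,
                      "soil", "snow", "stage"), "observations")
  mf <- data
  mf$temp <- data[[spec$temperature_var]]
  mf$cmiv <- data[[spec$moisture_var]]
  mf$soil <- droplevels(as_soil_class(as.character(mf$soil)))
  mf$snow <- droplevels(factor(as.character(mf$snow),
                               levels = bg_snow_classes()))
  mf$stage <- droplevels(factor(as.character(mf$stage),
                                levels = bg_stages()))
  for (f in c("soil", "snow", "stage")) {
    mf[[paste0(f, "_o")]] <- as.ordered(mf[[f]])
  }
  mf
}

# build the model formula, downgrading terms the data cannot support
build_formula <- function(mf, spec) {
  k <- spec$basis_dim; kt <- spec$tensor_dim
  notes <- character(0)
  smooth_of <- function(var) {
    nu <- length(unique(mf[[var]]))
    if (nu < 3) {
      notes <<- c(notes, sprintf("dropped s(%s): %d unique value(s)", var, nu))
      return(NULL)
    }
    ke <- min(k, nu - 1)
    if (ke < k) notes <<- c(notes, sprintf("s(%s) basis reduced to %d", var, ke))
    sprintf("s(%s, k = %d, bs = 'cr')", var, ke)
  }
  fac_ok <- vapply(c("soil", "snow", "stage"),
                   function(f) nlevels(mf[[f]]) >= 2, logical(1))
  for (f in names(fac_ok)[!fac_ok]) {
    notes <- c(notes, sprintf("dropped factor '%s': single level", f))
  }
  by_smooth <- function(var, fac) {
    if (!fac_ok[[fac]] || !spec$factor_smooths) return(NULL)
    if (length(unique(mf[[var]])) < 3) return(NULL)
    ke <- min(k, length(unique(mf[[var]])) - 1)
    sprintf("s(%s, by = %s_o, k = %d, bs = 'cr')", var, fac, ke)
  }
  terms <- c(
    "log(size)", "size",
    names(fac_ok)[fac_ok],
    smooth_of("age"), smooth_of("bal"), smooth_of("ba"), smooth_of("slope"),
    smooth_of("temp"), smooth_of("cmiv"),
    if (length(unique(mf$temp)) >= kt && length(unique(mf$cmiv)) >= kt)
      sprintf("te(temp, cmiv, k = c(%d, %d))", kt, kt),
    by_smooth("temp", "soil"), by_smooth("cmiv", "soil"),
    by_smooth("cmiv", "snow"),
    by_smooth("temp", "stage"), by_smooth("cmiv", "stage"),
    by_smooth("ba", "stage"), by_smooth("bal", "stage")
  )
  list(formula = stats::as.formula(
         paste("log(bai + 1) ~", paste(terms, collapse = " + "))),
       notes = notes)
}

#' Fit the growth model to tree observations
#'
#' Fits the [model_spec()] additive model by penalized likelihood with
#' smoothness chosen by REML (or the configured criterion), computes the
#' Duan smearing factor from the log-scale residuals, and records the fit
#' diagnostics and training-data summaries needed for prediction and
#' partial effects. Terms that the data cannot support (single-level
#' factors, near-constant covariates) are dropped automatically and the
#' downgrades recorded in `$notes`.
#'
#' @param observations Data.frame of tree observations (see
#'   [prepare_tree_observations()]); one species at a time.
#' @param spec A [model_spec()].
#' @param min_obs Minimum observations required (default 50).
#' @return Object of class `bg_growth_model`: the mgcv fit (`$fit`),
#'   smearing factor(s) (`$smearing`), metrics (`$metrics`: deviance
#'   explained %, RMSE % of the log-response range, AIC, n), training
#'   medians/modes (`$center`), observed covariate ranges (`$ranges`), the
#'   spec and downgrade notes.
#' @export
fit_growth_model <- function(observations, spec = model_spec(),
                             min_obs = 50) {
  if (nrow(observations) < min_obs) {
    stopf("fit_growth_model: %d observations < min_obs = %d",
          nrow(observations), min_obs)
  }
  mf <- model_frame(observations, spec)
  constant_response <- diff(range(log(mf$bai + 1))) < 1e-10
  if (constant_response) {
    # degenerate constant response: penalized smoothness selection is
    # undefined (zero scale); fall back to the intercept-only model
    fb <- list(formula = stats::as.formula("log(bai + 1) ~ 1"),
               notes = "constant response: intercept-only fit")
  } else {
    fb <- build_formula(mf, spec)
  }
  use_bam <- spec$engine == "bam" ||
    (spec$engine == "auto" && nrow(mf) > spec$bam_threshold)
  fit <- if (constant_response) {
    mgcv::gam(fb$formula, data = mf, method = "GCV.Cp")
  } else if (use_bam) {
    mgcv::bam(fb$formula, data = mf, method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(fb$formula, data = mf, method = spec$method)
  }
  res <- stats::residuals(fit)
  smear <- if (is.null(spec$smear_by)) {
    smearing_factor(res)
  } else {
    tapply(res, mf[[spec$smear_by]], smearing_factor)
  }
  y <- log(mf$bai + 1)
  yrange <- diff(range(y))
  metrics <- data.frame(
    dev_expl = summary(fit)$dev.expl * 100,
    rmse_pct = if (yrange > 0) sqrt(mean(res^2)) / yrange * 100 else 0,
    aic = stats::AIC(fit),
    n = nrow(mf)
  )
  num <- c("size", "age", "ba", "bal", "slope", "temp", "cmiv")
  center <- lapply(mf[num], stats::median)
  for (f in c("soil", "snow", "stage")) {
    tab <- table(mf[[f]])
    center[[f]] <- names(tab)[which.max(tab)]
  }
  ranges <- lapply(mf[num], range)
  structure(list(fit = fit, spec = spec, smearing = smear,
                 metrics = metrics, center = center, ranges = ranges,
                 response_range = yrange, notes = fb$notes,
                 levels = lapply(mf[c("soil", "snow", "stage")], levels)),
            class = "bg_growth_model")
}

#' @export
print.bg_growth_model <- function(x, ...) {
  cat("Additive growth model on log(BAI + 1)\n")
  cat(sprintf("  n = %d, deviance explained = %.1f%%, RMSE = %.1f%%, AIC = %.1f\n",
              x$metrics$n, x$metrics$dev_expl, x$metrics$rmse_pct,
              x$metrics$aic))
  s <- if (length(x$smearing) == 1L) sprintf("%.4f", x$smearing) else
    paste(sprintf("%s=%.4f", names(x$smearing), x$smearing), collapse = ", ")
  cat(sprintf("  smearing factor: %s\n", s))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Duan smearing factor
#'
#' The nonparametric retransformation factor `S = mean(exp(residuals))` of
#' a log-scale model; the bias-corrected back-transform of a prediction
#' `p` on the log(BAI + 1) scale is `exp(p) * S - 1`. With residuals
#' identically zero `S = 1`; with Normal(0, sigma^2) residuals `S`
#' converges to `exp(sigma^2 / 2)`.
#'
#' @param residuals Log-scale residuals, finite, length >= 2.
#' @return The smearing factor, a single number >= 0.
#' @export
smearing_factor <- function(residuals) {
  if (length(residuals) < 2L) stopf("smearing_factor: need >= 2 residuals")
  if (any(!is.finite(residuals))) stopf("smearing_factor: non-finite residuals")
  mean(exp(residuals))
}

# fold factor levels unseen in training back to the reference level
fold_levels <- function(x, levels, what) {
  x <- as.character(x)
  unseen <- setdiff(unique(x), levels)
  if (length(unseen) > 0L) {
    warnf("predict_bai: %s level(s) %s unseen in training; folded to '%s'",
          what, paste(unseen, collapse = ", "), levels[1])
    x[x %in% unseen] <- levels[1]
  }
  factor(x, levels = levels)
}

#' Predict BAI from a fitted growth model
#'
#' Evaluates the model on new covariates and back-transforms with the
#' smearing correction: `BAI = exp(eta) * S - 1`. Factor levels absent from
#' the training data are folded to the reference level with a warning.
#'
#' @param model A [fit_growth_model()] object.
#' @param newdata Data.frame with the covariate columns (`size`, `age`,
#'   `ba`, `bal`, `slope`, `soil`, `snow`, `stage` and the climate columns
#'   named by the spec, or pre-mapped `temp`/`cmiv`).
#' @param smear Apply the smearing correction (default `TRUE`); `FALSE`
#'   gives the naive `exp(eta) - 1` back-transform.
#' @return Predicted BAI, cm2 yr-1.
#' @export
predict_bai <- function(model, newdata, smear = TRUE) {
  stopifnot(inherits(model, "bg_growth_model"))
  spec <- model$spec
  nd <- newdata
  if (is.null(nd$temp)) {
    if (is.null(nd[[spec$temperature_var]])) {
      stopf("predict_bai: missing covariate '%s'", spec$temperature_var)
    }
    nd$temp <- nd[[spec$temperature_var]]
  }
  if (is.null(nd$cmiv)) {
    if (is.null(nd[[spec$moisture_var]])) {
      stopf("predict_bai: missing covariate '%s'", spec$moisture_var)
    }
    nd$cmiv <- nd[[spec$moisture_var]]
  }
  for (v in c("size", "age", "ba", "bal", "slope")) {
    if (is.null(nd[[v]])) stopf("predict_bai: missing covariate '%s'", v)
  }
  for (f in c("soil", "snow", "stage")) {
    if (is.null(nd[[f]])) stopf("predict_bai: missing covariate '%s'", f)
    nd[[f]] <- fold_levels(nd[[f]], model$levels[[f]], f)
    nd[[paste0(f, "_o")]] <- as.ordered(nd[[f]])
  }
  eta <- as.numeric(stats::predict(model$fit, newdata = nd,
                                   type = "response"))
  s <- if (!smear) 1 else if (length(model$smearing) == 1L) {
    model$smearing
  } else {
    sb <- model$spec$smear_by
    unname(model$smearing[as.character(newdata[[sb]])])
  }
  exp(eta) * s - 1
}

#' Partial-effect predictions over one or two covariates
#'
#' Predicts BAI over a grid of one or two covariates while holding all
#' remaining covariates at their training medians (numeric) or modal level
#' (factors) -- the construction behind single-variable threshold curves
#' and the temperature-moisture heat surfaces.
#'
#' @param model A [fit_growth_model()] object.
#' @param vars One or two of `"temp"`, `"cmiv"`, `"size"`, `"age"`, `"ba"`,
#'   `"bal"`, `"slope"`.
#' @param n Grid points per variable (default 50).
#' @param smear Passed to [predict_bai()].
#' @return Data.frame of the grid with a `bai` column.
#' @export
partial_effect <- function(model, vars, n = 50, smear = TRUE) {
  stopifnot(inherits(model, "bg_growth_model"),
            length(vars) %in% 1:2, all(vars %in% names(model$ranges)))
  grids <- lapply(vars, function(v) {
    r <- model$ranges[[v]]
    seq(r[1], r[2], length.out = n)
  })
  names(grids) <- vars
  nd <- expand.grid(grids)
  for (v in setdiff(names(model$center), vars)) nd[[v]] <- model$center[[v]]
  nd$bai <- predict_bai(model, nd, smear = smear)
  nd
}

#' Recover the fitted thermal optimum
#'
#' Location of the maximum of the temperature partial effect, evaluated on
#' a fine grid over the observed temperature range.
#'
#' @param model A [fit_growth_model()] object.
#' @param n Grid resolution (default 400).
#' @return Temperature (degC) at which the partial-effect BAI peaks.
#' @export
fitted_t_opt <- function(model, n = 400) {
  pe <- partial_effect(model, "temp", n = n, smear = FALSE)
  pe$temp[which.max(pe$bai)]
}

#' Select climate variables by AIC
#'
#' Fits the growth model for the four combinations of temperature
#' (`tmax`, `tmean`) and water-availability (`cmi_gs`, `cmi_summer`)
#' variables and returns the AIC-minimal pair. Ties break deterministically
#' in the declared order; failed fits are excluded with a warning.
#'
#' @param observations Tree observations containing all four candidate
#'   columns.
#' @param spec Base [model_spec()]; its climate-variable fields are
#'   overridden per combination.
#' @param ... Passed to [fit_growth_model()].
#' @return List with `best` (character two-vector), `table` (data.frame of
#'   combination AICs) and `models` (the fitted models).
#' @export
select_climate_variables <- function(observations, spec = model_spec(), ...) {
  combos <- list(c("tmax", "cmi_gs"), c("tmax", "cmi_summer"),
                 c("tmean", "cmi_gs"), c("tmean", "cmi_summer"))
  fits <- vector("list", length(combos))
  aics <- rep(NA_real_, length(combos))
  for (i in seq_along(combos)) {
    sp <- spec
    sp$temperature_var <- combos[[i]][1]
    sp$moisture_var <- combos[[i]][2]
    fits[[i]] <- tryCatch(fit_growth_model(observations, sp, ...),
                          error = function(e) {
                            warnf("select_climate_variables: combination %s + %s failed: %s",
                                  combos[[i]][1], combos[[i]][2],
                                  conditionMessage(e))
                            NULL
                          })
    if (!is.null(fits[[i]])) aics[i] <- fits[[i]]$metrics$aic
  }
  if (all(is.na(aics))) stopf("select_climate_variables: every combination failed")
  tab <- data.frame(
    temperature = vapply(combos, `[`, character(1), 1),
    moisture = vapply(combos, `[`, character(1), 2),
    aic = aics
  )
  best <- which.min(aics)  # first minimum: deterministic tie-break
  list(best = combos[[best]], table = tab, models = fits)
}

#' Validate the growth model on a held-out split
#'
#' Fits the model on a random subset (default 80%) of the trees and
#' evaluates predictions on the remainder: deviance explained (%) and RMSE
#' on the training fit, and test-set RMSE. RMSE is the log-response-scale
#' root mean square error expressed as a percentage of the training
#' log-response range.
#'
#' @param observations Tree observations.
#' @param spec A [model_spec()].
#' @param split Training fraction (default 0.8).
#' @param seed Integer seed for the split.
#' @param ... Passed to [fit_growth_model()].
#' @return List with `dev_expl`, `rmse_pct`, `test_rmse_pct`, `n_train`,
#'   `n_test`, and the training `model`.
#' @export
validate_growth_model <- function(observations, spec = model_spec(),
                                  split = 0.8, seed = 1, ...) {
  n <- nrow(observations)
  set.seed(seed)
  idx <- sample.int(n, size = floor(split * n))
  if (length(idx) == 0L || length(idx) == n) {
    stopf("validate_growth_model: split %g leaves an empty partition at n = %d",
          split, n)
  }
  train <- observations[idx, , drop = FALSE]
  test <- observations[-idx, , drop = FALSE]
  model <- fit_growth_model(train, spec, ...)
  yr <- model$response_range
  if (yr <= 0) yr <- 1  # degenerate constant response
  obs_log <- log(test$bai + 1)
  pred <- predict_bai(model, test, smear = FALSE)
  pred_log <- log(pmax(pred, 0) + 1)
  list(
    dev_expl = model$metrics$dev_expl,
    rmse_pct = model$metrics$rmse_pct,
    test_rmse_pct = sqrt(mean((obs_log - pred_log)^2)) / yr * 100,
    n_train = nrow(train), n_test = nrow(test),
    model = model
  )
}

#' Export a fitted model's summary to JSON
#'
#' Writes coefficients, smearing factor(s), metrics, covariate centers and
#' ranges to a JSON file (the mgcv object itself is not serialised).
#'
#' @param model A [fit_growth_model()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_model_json <- function(model, path) {
  obj <- list(
    coefficients = as.list(stats::coef(model$fit)),
    smearing = as.list(model$smearing),
    metrics = as.list(model$metrics),
    center = model$center,
    ranges = model$ranges,
    spec = unclass(model$spec),
    notes = model$notes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
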