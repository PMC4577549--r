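# Retrospective forecast evaluation: fit each model on a base period,
# forecast a held-out horizon, score the predictive median e0 against the
# observed series with per-year forecast errors and their mean absolute
# error. A model that fails raises a typed condition which is recorded as an
# error-status row; the other models still run.

#' Per-year forecast errors
#'
#' `FE(t) = forecast(t) - observed(t)`: positive values mean the forecast
#' overestimates observed life expectancy (bias with sign).
#'
#' @param forecast_e0 per-year forecast medians, named by year (or aligned).
#' @param observed_e0 per-year observed values on the same year grid.
#' @return numeric vector of forecast errors.
#' @export
forecast_errors <- function(forecast_e0, observed_e0) {
  if (length(forecast_e0) != length(observed_e0))
    abort_rmicast("alignment_error", "year grids differ in length")
  nf <- names(forecast_e0); no <- names(observed_e0)
  if (!is.null(nf) && !is.null(no) && !identical(nf, no))
    abort_rmicast("alignment_error", "year grids differ")
  forecast_e0 - observed_e0
}

#' Mean absolute forecast error
#'
#' @param errors nonempty numeric vector of per-year forecast errors.
#' @return the mean of the absolute errors, in years.
#' @export
mae <- function(errors) {
  if (length(errors) == 0)
    abort_rmicast("domain_error", "MAE of an empty error vector")
  mean(abs(errors))
}

#' Run a retrospective forecast evaluation
#'
#' Subsets `observed` to the base period, fits every requested model, and
#' scores its median e0 forecast on the held-out years
#' `(base[2]+1):horizon_end`. Built-in models are `"lee_carter"`,
#' `"li_lee"` and `"rmi"`; entries of `models` may also be functions
#' `f(base_surface, references, horizon_years, n_draws, seed)` returning a
#' per-year median e0 vector (useful for stubs and custom baselines).
#'
#' @param observed a [mortality_surface()] covering base period and horizon.
#' @param base inclusive `c(first, last)` base-period years.
#' @param horizon_end last forecast year to score.
#' @param models character names and/or named list mixing names and
#'   functions.
#' @param references named list, keyed by model name, of lists of reference
#'   `mortality_surface`s (full-span; they are subset to the base period).
#'   `li_lee` pools them with the target; `rmi` blends their trends.
#' @param n_draws,seed simulation settings shared by all models.
#' @param config an [rmi_config()] for the `rmi` model.
#' @param a0,a_interior life-table conventions for observed and forecast e0.
#' @return an object of class `evaluation_report`: per-model `status`
#'   (`"ok"` or `"error:<type>"`), per-year `fe`, `mae`, plus echoes of the
#'   design (`base`, `horizon_years`) and configs.
#' @export
run_retrospective <- function(observed, base, horizon_end,
                              models = c("lee_carter", "li_lee", "rmi"),
                              references = list(), n_draws = 500, seed = 1,
                              config = rmi_config(), a0 = 0.1,
                              a_interior = 0.5) {
  validate_surface(observed)
  if (horizon_end <= base[2])
    abort_rmicast("domain_error", "horizon must extend beyond the base period")
  if (base[1] < min(observed$years) || horizon_end > max(observed$years))
    abort_rmicast("domain_error", sprintf(
      "cannot score: need observed data %d-%d, have %d-%d",
      base[1], horizon_end, min(observed$years), max(observed$years)))
  horizon_years <- (base[2] + 1):horizon_end
  H <- length(horizon_years)
  base_surface <- subset_surface(observed, year_range = base)
  obs_e0 <- e0_series(subset_surface(observed,
                                     year_range = c(base[2] + 1, horizon_end)),
                      a0 = a0, a_interior = a_interior)

  if (is.character(models)) models <- stats::setNames(as.list(models), models)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m)
      if (is.character(m)) m else "custom", "")

  run_one <- function(m, refs) {
    if (is.function(m))
      return(m(base_surface, refs, horizon_years, n_draws, seed))
    refs_base <- lapply(refs, subset_surface, year_range = base)
    switch(m,
      lee_carter = {
        fc <- forecast_lc(fit_lc(base_surface), H, n_draws, seed,
                          a0 = a0, a_interior = a_interior)
        median_e0(fc)
      },
      li_lee = {
        if (length(refs_base) == 0)
          abort_rmicast("domain_error", "li_lee needs reference populations")
        fit <- fit_li_lee(c(list(base_surface), refs_base))
        fc <- forecast_li_lee(fit, H, n_draws, seed,
                              a0 = a0, a_interior = a_interior)
        median_e0(fc[[base_surface$population]])
      },
      rmi = {
        fit <- fit_rmi(base_surface, refs_base, config, seed = seed)
        median_e0(forecast_rmi(fit, H, n_draws, seed))
      },
      abort_rmicast("config_error", sprintf("unknown model '%s'", m)))
  }

  results <- list()
  for (nm in names(models)) {
    refs <- if (!is.null(references[[nm]])) references[[nm]] else list()
    res <- tryCatch({
      fc_e0 <- suppressWarnings(run_one(models[[nm]], refs))
      names(fc_e0) <- horizon_years
      fe <- forecast_errors(fc_e0, obs_e0)
      list(status = "ok", fe = fe, mae = mae(fe))
    }, rmicast_error = function(e) {
      list(status = paste0("error:", class(e)[1]), fe = NULL, mae = NA_real_)
    })
    results[[nm]] <- res
  }
  structure(
    list(population = observed$population, sex = observed$sex,
         models = results, base = base, horizon_years = horizon_years,
         n_draws = n_draws, seed = seed, config = config,
         observed_e0 = obs_e0),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (%s): base %d-%d, scored %d-%d\n",
              x$population, x$sex, x$base[1], x$base[2],
              min(x$horizon_years), max(x$horizon_years)))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    if (m$status == "ok")
      cat(sprintf("  %-12s MAE %.3f\n", nm, m$mae))
    else
      cat(sprintf("  %-12s %s\n", nm, m$status))
  }
  invisible(x)
}

#' Evaluation report as long data frames
#'
#' @param report an `evaluation_report`.
#' @return list of two data frames: `errors` (per-year FE long table) and
#'   `mae` (one row per model with status).
#' @export
report_tables <- function(report) {
  err <- do.call(rbind, lapply(names(report$models), function(nm) {
    m <- report$models[[nm]]
    if (is.null(m$fe)) return(NULL)
    data.frame(population = report$population, sex = report$sex, model = nm,
               year = as.integer(names(m$fe)), fe = unname(m$fe))
  }))
  summ <- do.call(rbind, lapply(names(report$models), function(nm) {
    m <- report$models[[nm]]
    data.frame(population = report$population, sex = report$sex, model = nm,
               status = m$status, mae = m$mae)
  }))
  list(errors = err, mae = summ)
}
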