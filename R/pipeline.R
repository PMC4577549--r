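# Config-driven entry point: simulate or load data, fit and forecast or run
# the retrospective evaluation, write CSV tables, figures, and a run log
# echoing every resolved parameter. Identical config + seed gives identical
# numeric output.

require_key <- function(cfg, key, where = "config") {
  if (is.null(cfg[[key]]))
    abort_rmicast("config_error",
                  sprintf("missing %s key '%s'", where, key))
  cfg[[key]]
}

#' Run the forecasting pipeline from a configuration
#'
#' The configuration is a list (or path to a JSON file) with keys:
#' \describe{
#'   \item{data}{`list(source = "scenario", preset = ..., seed = ...)` to
#'     simulate, or `list(source = "csv", target = <path>, references =
#'     <paths>)` to read internal long CSVs.}
#'   \item{models}{character vector among `"lee_carter"`, `"li_lee"`,
#'     `"rmi"`.}
#'   \item{design}{`list(type = "retrospective", base = c(y0, y1),
#'     horizon_end = y2)` or `list(type = "prospective", base = c(y0, y1),
#'     horizon = H)`.}
#'   \item{n_draws, seed}{simulation settings (defaults 500, 1).}
#'   \item{rmi}{optional list of [rmi_config()] overrides.}
#' }
#'
#' @param config list or path to a JSON config file.
#' @param out_dir output directory (created if needed); `NULL` disables all
#'   file output.
#' @return invisibly, a list with the evaluation report and/or forecasts,
#'   the quantile table, and the resolved config.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  data_cfg <- require_key(config, "data")
  models <- require_key(config, "models")
  design <- require_key(config, "design")
  type <- require_key(design, "type", "design")
  base <- require_key(design, "base", "design")
  n_draws <- if (is.null(config$n_draws)) 500 else config$n_draws
  seed <- if (is.null(config$seed)) 1 else config$seed
  rmi_cfg <- do.call(rmi_config, as.list(config$rmi))

  src <- require_key(data_cfg, "source", "data")
  if (src == "scenario") {
    scen_seed <- if (is.null(data_cfg$seed)) seed else data_cfg$seed
    scen <- generate_scenario(scenario_config(
      preset = require_key(data_cfg, "preset", "data"), seed = scen_seed))
    target <- scen$target; references <- scen$references
  } else if (src == "csv") {
    target <- read_surface_csv(require_key(data_cfg, "target", "data"))
    references <- lapply(as.character(data_cfg$references), read_surface_csv)
  } else {
    abort_rmicast("config_error", sprintf("unknown data source '%s'", src))
  }
  refs <- stats::setNames(rep(list(references), length(models)), models)

  out <- list(config = config)
  if (type == "retrospective") {
    horizon_end <- require_key(design, "horizon_end", "design")
    rep_ <- run_retrospective(target, base = base, horizon_end = horizon_end,
                              models = models, references = refs,
                              n_draws = n_draws, seed = seed,
                              config = rmi_cfg)
    out$report <- rep_
    out$tables <- report_tables(rep_)
  } else if (type == "prospective") {
    horizon <- require_key(design, "horizon", "design")
    base_surface <- subset_surface(target, year_range = base)
    refs_base <- lapply(references, subset_surface, year_range = base)
    fcs <- list()
    for (m in models) {
      fcs[[m]] <- switch(m,
        lee_carter = forecast_lc(fit_lc(base_surface), horizon, n_draws, seed),
        rmi = forecast_rmi(fit_rmi(base_surface, refs_base, rmi_cfg,
                                   seed = seed), horizon, n_draws, seed),
        li_lee = forecast_li_lee(fit_li_lee(c(list(base_surface), refs_base)),
                                 horizon, n_draws,
                                 seed)[[base_surface$population]],
        abort_rmicast("config_error", sprintf("unknown model '%s'", m)))
    }
    out$forecasts <- fcs
    out$quantiles <- as_quantile_table(
      stats::setNames(fcs, paste(target$population, names(fcs), sep = ":")),
      sex = target$sex)
  } else {
    abort_rmicast("config_error", sprintf("unknown design type '%s'", type))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$tables)) {
      utils::write.csv(out$tables$errors,
                       file.path(out_dir, "evaluation_errors.csv"),
                       row.names = FALSE)
      utils::write.csv(out$tables$mae,
                       file.path(out_dir, "evaluation_mae.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$quantiles))
      write_quantile_csv(out$quantiles, file.path(out_dir, "quantiles.csv"))
    grDevices::png(file.path(out_dir, "lexis_bands.png"), 900, 600)
    plot_lexis_bands(improvement_rates(target))
    grDevices::dev.off()
    if (!is.null(out$forecasts) && length(out$forecasts)) {
      grDevices::png(file.path(out_dir, "fan_chart.png"), 900, 600)
      plot_fan(out$forecasts[[length(out$forecasts)]],
               observed = e0_series(target))
      grDevices::dev.off()
    }
    log <- list(config = config, n_draws = n_draws, seed = seed,
                rmi_config = unclass(rmi_cfg),
                models = models, design = design,
                timestamp = "deterministic")
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}
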