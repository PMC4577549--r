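# Quantile tables of forecasted life expectancy: rows keyed by
# (population, sex, quantile level), columns by year. The wide CSV layout
# mirrors the conventional published table of forecasted e0 quantiles.

#' Build a quantile table
#'
#' @param population,sex,level,years,values parallel inputs: `values` is a
#'   numeric matrix with one row per (population, sex, level) key and one
#'   column per year.
#' @return a `data.frame` of class `quantile_table` with columns
#'   `population`, `sex`, `level`, then one numeric column per year.
#' @export
quantile_table <- function(population, sex, level, years, values) {
  values <- as.matrix(values)
  df <- data.frame(population = population, sex = sex, level = level,
                   values, check.names = FALSE)
  names(df)[-(1:3)] <- as.character(years)
  for (key in unique(paste(df$population, df$sex))) {
    rows <- df[paste(df$population, df$sex) == key, ]
    rows <- rows[order(rows$level), ]
    if (any(apply(as.matrix(rows[, -(1:3), drop = FALSE]), 2, is.unsorted)))
      abort_rmicast("domain_error", sprintf(
        "quantile values not non-decreasing in level for %s", key))
  }
  class(df) <- c("quantile_table", "data.frame")
  df
}

#' Quantile table from forecast results
#'
#' @param forecasts named list of `forecast_result` objects (names are
#'   population codes) or a single `forecast_result`.
#' @param sex sex label for the rows.
#' @param levels quantile levels to include (default 0.025, 0.5, 0.975).
#' @param years subset of forecast years (default: all).
#' @return a `quantile_table`.
#' @export
as_quantile_table <- function(forecasts, sex = "total",
                              levels = c(0.025, 0.5, 0.975), years = NULL) {
  if (inherits(forecasts, "forecast_result"))
    forecasts <- stats::setNames(list(forecasts), forecasts$population)
  rows <- list()
  for (nm in names(forecasts)) {
    fc <- forecasts[[nm]]
    yrs <- if (is.null(years)) fc$years else intersect(years, fc$years)
    li <- match(levels, fc$levels)
    if (anyNA(li))
      abort_rmicast("lookup_error", "requested level not in forecast")
    rows[[nm]] <- data.frame(
      population = nm, sex = sex, level = levels,
      fc$e0_quantiles[li, as.character(yrs), drop = FALSE],
      check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("quantile_table", "data.frame")
  out
}

#' Write / read a quantile table as wide CSV
#'
#' Layout: columns `population, sex, level`, then one column per year.
#' Values round-trip to better than 1e-12.
#'
#' @param q a `quantile_table`.
#' @param path file path.
#' @export
write_quantile_csv <- function(q, path) {
  df <- as.data.frame(q)
  for (j in seq(4, ncol(df)))
    df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_quantile_csv
#' @export
read_quantile_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("population", "sex", "level")
  if (!all(need %in% names(df)))
    abort_rmicast("parse_error", "quantile CSV needs population, sex, level")
  class(df) <- c("quantile_table", "data.frame")
  df
}

qt_lookup <- function(q, population, sex, level, year) {
  i <- which(q$population == population & q$sex == sex &
             abs(q$level - level) < 1e-9)
  ycol <- as.character(year)
  if (length(i) != 1 || !ycol %in% names(q))
    abort_rmicast("lookup_error", sprintf(
      "no entry for (%s, %s, %s, %s)", population, sex, level, year))
  q[[ycol]][i]
}

# half-away-from-zero rounding to integers ("round half up" in magnitude),
# the convention used when quoting interval widths and gains in whole years
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Prediction-interval width from a quantile table
#'
#' @param q a `quantile_table`.
#' @param population,sex,year row/column keys.
#' @param level_low,level_high quantile levels, `level_high > level_low`.
#' @param rounding `"none"` (default) or `"integer"` (half-away-from-zero).
#' @return width in years.
#' @examples
#' # a 95% interval width is value(0.975) - value(0.025)
#' @export
interval_width <- function(q, population, sex, year, level_low = 0.025,
                           level_high = 0.975,
                           rounding = c("none", "integer")) {
  rounding <- match.arg(rounding)
  if (level_high < level_low)
    abort_rmicast("domain_error", "level_high must be >= level_low")
  w <- qt_lookup(q, population, sex, level_high, year) -
       qt_lookup(q, population, sex, level_low, year)
  if (rounding == "integer") round_half_away(w) else w
}

#' Life-expectancy gain between two years at a quantile level
#'
#' @inheritParams interval_width
#' @param year_from,year_to calendar years.
#' @param level quantile level (default 0.5, the median).
#' @return gain in years (`value(year_to) - value(year_from)`).
#' @export
e0_gain <- function(q, population, sex, year_from, year_to, level = 0.5,
                    rounding = c("none", "integer")) {
  rounding <- match.arg(rounding)
  g <- qt_lookup(q, population, sex, level, year_to) -
       qt_lookup(q, population, sex, level, year_from)
  if (rounding == "integer") round_half_away(g) else g
}
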