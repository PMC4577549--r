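# Shared container for probabilistic forecasts: per-year quantiles of e0 and
# of the age-specific death rates, computed from simulated draws.

FORECAST_LEVELS <- c(0.025, 0.10, 0.165, 0.25, 0.5, 0.75, 0.835, 0.90, 0.975)

# rate_draws: array draws x ages x horizon (may be NULL)
# e0_draws:   matrix draws x horizon
new_forecast_result <- function(population, years, e0_draws, rate_draws = NULL,
                                n_draws, seed, levels = FORECAST_LEVELS,
                                extras = list()) {
  e0_q <- apply(e0_draws, 2, stats::quantile, probs = levels, names = FALSE)
  if (is.null(dim(e0_q))) e0_q <- matrix(e0_q, nrow = length(levels))
  dimnames(e0_q) <- list(levels, years)
  rate_q <- NULL
  if (!is.null(rate_draws)) {
    rate_q <- apply(rate_draws, c(2, 3), stats::quantile, probs = levels,
                    names = FALSE)
    dimnames(rate_q)[[1]] <- levels
    dimnames(rate_q)[[3]] <- years
  }
  structure(
    list(population = population, years = years, levels = levels,
         e0_quantiles = e0_q, rate_quantiles = rate_q,
         n_draws = n_draws, seed = seed, extras = extras),
    class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> %s: %d-%d (%d draws)\n", x$population,
              min(x$years), max(x$years), x$n_draws))
  cat("  median e0:", paste(sprintf("%.2f", x$e0_quantiles["0.5", ]),
                            collapse = " "), "\n")
  invisible(x)
}

#' Extract the median e0 path of a forecast
#'
#' @param fc a `forecast_result`.
#' @return named numeric vector (years) of median life expectancy at birth.
#' @export
median_e0 <- function(fc) {
  out <- fc$e0_quantiles["0.5", ]
  names(out) <- fc$years
  out
}
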