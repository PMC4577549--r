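# Visual output: Lexis heat maps of improvement bands and fan charts of
# forecasted e0. Purely illustrative; no numbers are derived from these.

#' Lexis heat map of improvement-rate bands
#'
#' Strong improvements (> 4 %/yr) in red, moderate (0.5--4 %) in green,
#' stagnation (-0.5 to +0.5 %) in white, deterioration (< -0.5 %) in grey.
#'
#' @param imp an `improvement_surface` from [improvement_rates()].
#' @param main plot title.
#' @export
plot_lexis_bands <- function(imp, main = "Rates of mortality improvement") {
  band <- matrix(classify_bands(imp$rho), nrow = nrow(imp$rho))
  lev <- c("deteriorating", "stagnating", "moderate", "strong")
  z <- matrix(match(band, lev), nrow = nrow(band))
  graphics::image(x = imp$years, y = imp$ages, z = t(z), zlim = c(1, 4),
                  col = c("grey35", "white", "forestgreen", "firebrick"),
                  xlab = "Year", ylab = "Age", main = main, useRaster = TRUE)
  graphics::box()
  invisible(NULL)
}

#' Fan chart of forecasted life expectancy
#'
#' Shades the 80, 67 and 50 % prediction intervals, lightening toward the
#' dashed median; optionally prepends an observed series.
#'
#' @param fc a `forecast_result`.
#' @param observed optional named numeric vector of observed e0 (names are
#'   years), drawn in black before the forecast.
#' @param main plot title.
#' @export
plot_fan <- function(fc, observed = NULL, main = "Forecasted e0") {
  q <- fc$e0_quantiles
  yrs <- fc$years
  xr <- range(c(yrs, if (!is.null(observed)) as.numeric(names(observed))))
  yr_ <- range(c(q, observed))
  graphics::plot(NA, xlim = xr, ylim = yr_, xlab = "Year",
                 ylab = "e0 (years)", main = main)
  bands <- list(c("0.1", "0.9", "#c6dbef"), c("0.165", "0.835", "#9ecae1"),
                c("0.25", "0.75", "#6baed6"))
  for (b in bands) {
    lo <- q[b[1], ]; hi <- q[b[2], ]
    graphics::polygon(c(yrs, rev(yrs)), c(lo, rev(hi)), col = b[3],
                      border = NA)
  }
  graphics::lines(yrs, q["0.5", ], lty = 2, lwd = 2)
  if (!is.null(observed))
    graphics::lines(as.numeric(names(observed)), observed, lwd = 2)
  invisible(NULL)
}
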