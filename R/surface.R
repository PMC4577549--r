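#' Construct a mortality surface
#'
#' A `mortality_surface` is the universal input of the package: an age-by-year
#' grid of central death rates for one population and sex, optionally carrying
#' the death counts and person-year exposures the rates were computed from.
#' Ages and years must be contiguous integer sequences; the last age may be
#' flagged as an open interval (e.g. "110+").
#'
#' @param rates numeric matrix of central death rates, `length(ages)` rows by
#'   `length(years)` columns. May be `NULL` if both `deaths` and `exposures`
#'   are given, in which case rates are derived as `deaths / exposures`.
#' @param ages integer vector of ages, strictly increasing by 1.
#' @param years integer vector of calendar years, strictly increasing by 1.
#' @param deaths optional matrix of death counts (>= 0), same shape as `rates`.
#' @param exposures optional matrix of person-years (> 0), same shape.
#' @param population short population code, e.g. `"ESP"`.
#' @param sex one of `"female"`, `"male"`, `"total"`.
#' @param open_interval logical; is the last age an open interval?
#' @return an object of class `mortality_surface`.
#' @examples
#' m <- matrix(0.01, nrow = 3, ncol = 2)
#' mortality_surface(m, ages = 0:2, years = 2000:2001, population = "TOY")
#' @export
mortality_surface <- function(rates = NULL, ages, years, deaths = NULL,
                              exposures = NULL, population = "unknown",
                              sex = c("female", "male", "total"),
                              open_interval = TRUE) {
  sex <- match.arg(sex)
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (is.null(rates)) {
    if (is.null(deaths) || is.null(exposures))
      abort_rmicast("domain_error",
                    "rates absent: need both deaths and exposures to derive them")
    rates <- deaths / exposures
  }
  rates <- as.matrix(rates)
  dimnames(rates) <- list(ages, years)
  if (!is.null(deaths)) dimnames(deaths) <- list(ages, years)
  if (!is.null(exposures)) dimnames(exposures) <- list(ages, years)
  s <- structure(
    list(population = population, sex = sex, ages = ages, years = years,
         rates = rates, deaths = deaths, exposures = exposures,
         open_interval = isTRUE(open_interval)),
    class = "mortality_surface"
  )
  validate_surface(s)
  s
}

#' Validate a mortality surface
#'
#' Checks the invariants of the container: contiguous integer axes, matching
#' matrix shapes, strictly positive finite rates, and consistency of rates
#' with `deaths / exposures` (to 1e-12) when both are present.
#'
#' @param s a `mortality_surface`.
#' @return `s`, invisibly, if valid; otherwise a typed error is thrown.
#' @export
validate_surface <- function(s) {
  if (!inherits(s, "mortality_surface"))
    abort_rmicast("domain_error", "not a mortality_surface")
  na <- length(s$ages); ny <- length(s$years)
  if (na > 1 && any(diff(s$ages) != 1L))
    abort_rmicast("contiguity_error", "ages must increase by exactly 1")
  if (ny > 1 && any(diff(s$years) != 1L))
    abort_rmicast("contiguity_error", "years must increase by exactly 1")
  if (!all(dim(s$rates) == c(na, ny)))
    abort_rmicast("domain_error", sprintf(
      "rates matrix is %dx%d, expected %dx%d",
      nrow(s$rates), ncol(s$rates), na, ny))
  if (any(!is.finite(s$rates)) || any(s$rates <= 0))
    abort_rmicast("domain_error", "all rates must be finite and > 0")
  for (nm in c("deaths", "exposures")) {
    mat <- s[[nm]]
    if (!is.null(mat)) {
      if (!all(dim(mat) == c(na, ny)))
        abort_rmicast("domain_error", sprintf("%s shape mismatch", nm))
      if (nm == "deaths" && any(mat < 0))
        abort_rmicast("domain_error", "deaths must be >= 0")
      if (nm == "exposures" && any(mat <= 0))
        abort_rmicast("domain_error", "exposures must be > 0")
    }
  }
  if (!is.null(s$deaths) && !is.null(s$exposures)) {
    if (max(abs(s$rates - s$deaths / s$exposures)) > 1e-12)
      abort_rmicast("domain_error",
                    "rates inconsistent with deaths/exposures beyond 1e-12")
  }
  invisible(s)
}

#' Subset a mortality surface by year and age ranges
#'
#' Extracts a contiguous sub-grid, e.g. the 1965--1990 base period of a
#' retrospective forecast design. All matrices (rates, deaths, exposures) are
#' sliced consistently.
#'
#' @param s a `mortality_surface`.
#' @param year_range inclusive `c(first, last)` pair, or `NULL` for all years.
#' @param age_range inclusive `c(first, last)` pair, or `NULL` for all ages.
#' @return a `mortality_surface` covering exactly the requested ranges.
#' @export
subset_surface <- function(s, year_range = NULL, age_range = NULL) {
  validate_surface(s)
  if (is.null(year_range)) year_range <- range(s$years)
  if (is.null(age_range)) age_range <- range(s$ages)
  if (year_range[1] < min(s$years) || year_range[2] > max(s$years))
    abort_rmicast("out_of_range_error", sprintf(
      "requested years %d-%d outside available %d-%d",
      year_range[1], year_range[2], min(s$years), max(s$years)))
  if (age_range[1] < min(s$ages) || age_range[2] > max(s$ages))
    abort_rmicast("out_of_range_error", sprintf(
      "requested ages %d-%d outside available %d-%d",
      age_range[1], age_range[2], min(s$ages), max(s$ages)))
  yi <- which(s$years >= year_range[1] & s$years <= year_range[2])
  ai <- which(s$ages >= age_range[1] & s$ages <= age_range[2])
  sl <- function(mat) if (is.null(mat)) NULL else mat[ai, yi, drop = FALSE]
  mortality_surface(
    rates = sl(s$rates), ages = s$ages[ai], years = s$years[yi],
    deaths = sl(s$deaths), exposures = sl(s$exposures),
    population = s$population, sex = s$sex,
    open_interval = s$open_interval && age_range[2] == max(s$ages)
  )
}

#' @export
print.mortality_surface <- function(x, ...) {
  cat(sprintf("<mortality_surface> %s (%s)\n", x$population, x$sex))
  cat(sprintf("  ages  %d-%d%s, years %d-%d\n",
              min(x$ages), max(x$ages), if (x$open_interval) "+" else "",
              min(x$years), max(x$years)))
  cat(sprintf("  rates in [%.3g, %.3g]%s%s\n",
              min(x$rates), max(x$rates),
              if (!is.null(x$deaths)) ", with deaths" else "",
              if (!is.null(x$exposures)) ", with exposures" else ""))
  invisible(x)
}
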