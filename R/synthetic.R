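# Synthetic mortality worlds. The generator specifies the truth in
# improvement-rate space and cumulates it into a rate surface, so the
# estimand of the improvement-rate model is known exactly. Three presets
# emulate the regimes that make forecasting hard: a regular decline with a
# dynamic age shift, a long stagnation followed by recovery (the Hungarian
# pattern), and a working-age mortality crisis followed by recovery (the
# Russian pattern). Reference populations experience the same latent field
# `lag` years earlier, which is what makes them informative about trend
# changes the target has not yet completed.

#' Gompertz-Makeham baseline hazard
#'
#' `m(x) = c + a exp(b x)`: a constant background risk plus an
#' exponentially increasing senescent component.
#'
#' @param ages integer ages.
#' @param c background (Makeham) term, >= 0.
#' @param a level of the senescent term, > 0.
#' @param b log-slope of the senescent term, > 0.
#' @return numeric vector of death rates.
#' @export
gompertz_makeham <- function(ages, c = 3e-4, a = 3e-5, b = 0.105) {
  if (c < 0 || a <= 0 || b <= 0)
    abort_rmicast("domain_error", "need c >= 0, a > 0, b > 0")
  c + a * exp(b * ages)
}

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe an HMD-like national population: ages 0--110 (110 open),
#' 60 years from 1950, a Gompertz-Makeham baseline with an infant term,
#' a Gaussian-in-age improvement field whose peak drifts from age 40 to age
#' 70 over the window (base level 1 %, peak 2.5 %, bandwidth 25 years of
#' age), constant exposure of 1e5 person-years per age, and Poisson death
#' counts. Regime windows add age- and period-specific shocks to the
#' improvement field.
#'
#' @param preset `"regular"`, `"stagnation-recovery"` or `"crisis-recovery"`;
#'   fills `regimes` accordingly (explicit `regimes` override the preset).
#' @param ages,n_years,start_year grid definition.
#' @param baseline list: Gompertz-Makeham `a`, `b`, `c` plus `infant` level
#'   and `infant_decay` for an `infant * exp(-decay x)` term.
#' @param improvement list: `base` and `peak` levels (percent per year),
#'   `peak_age_start`, `peak_age_end`, `bandwidth` (ages).
#' @param regimes list of `list(years = c(from, to), ages = c(from, to),
#'   shock = percent)` entries, calendar years, added to the field.
#' @param exposures scalar or per-age person-years (default 1e5).
#' @param noise `"poisson"` or `"none"`.
#' @param reference list: `lag` (years the references lead the target),
#'   `attenuation` of the field, `level_factor` on the baseline, `n`
#'   (number of reference populations).
#' @param seed RNG seed.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(preset = c("regular", "stagnation-recovery",
                                       "crisis-recovery"),
                            ages = 0:110, n_years = 60, start_year = 1950,
                            baseline = list(), improvement = list(),
                            regimes = NULL, exposures = 1e5,
                            noise = c("poisson", "none"),
                            reference = list(), seed = 1) {
  preset <- match.arg(preset)
  noise <- match.arg(noise)
  bl <- utils::modifyList(list(a = 3e-5, b = 0.105, c = 3e-4,
                               infant = 0.02, infant_decay = 0.45), baseline)
  im <- utils::modifyList(list(base = 1.0, peak = 2.5, peak_age_start = 40,
                               peak_age_end = 70, bandwidth = 25), improvement)
  rf <- utils::modifyList(list(lag = 10, attenuation = 1.0,
                               level_factor = 1.15, n = 1), reference)
  yr <- function(i) start_year + i - 1L
  if (is.null(regimes)) {
    regimes <- switch(preset,
      "regular" = list(),
      "stagnation-recovery" = list(
        list(years = c(yr(16), yr(45)), ages = range(ages), shock = -im$peak),
        list(years = c(yr(46), yr(n_years)), ages = range(ages), shock = 1.5)),
      "crisis-recovery" = list(
        # the crisis halts improvement at every age and reverses it hardest
        # at working ages (shocks on overlapping windows stack)
        list(years = c(yr(41), yr(50)), ages = range(ages), shock = -3.5),
        list(years = c(yr(41), yr(50)), ages = c(15, 60), shock = -4),
        list(years = c(yr(51), yr(n_years)), ages = range(ages), shock = 2)))
  }
  years <- seq(start_year, by = 1L, length.out = n_years)
  for (rg in regimes) {
    if (rg$years[1] < start_year || rg$years[2] > max(years) ||
        rg$ages[1] < min(ages) || rg$ages[2] > max(ages))
      abort_rmicast("config_error", "regime window outside the grid")
  }
  structure(list(preset = preset, ages = as.integer(ages),
                 n_years = as.integer(n_years),
                 start_year = as.integer(start_year), years = years,
                 baseline = bl, improvement = im, regimes = regimes,
                 exposures = exposures, noise = noise, reference = rf,
                 seed = seed),
            class = "scenario_config")
}

# True improvement field (percent/year) for the transitions ending in the
# given calendar years; evaluable beyond the grid (linear peak-age
# continuation) so reference populations can lead the target.
scenario_field <- function(cfg, cal_years) {
  im <- cfg$improvement
  frac <- (cal_years - cfg$start_year) / max(cfg$n_years - 1, 1)
  peak_age <- im$peak_age_start + (im$peak_age_end - im$peak_age_start) * frac
  G <- exp(-outer(cfg$ages, peak_age, `-`)^2 / (2 * im$bandwidth^2))
  F <- im$base + im$peak * G
  for (rg in cfg$regimes) {
    in_y <- cal_years >= rg$years[1] & cal_years <= rg$years[2]
    in_a <- cfg$ages >= rg$ages[1] & cfg$ages <= rg$ages[2]
    F[in_a, in_y] <- F[in_a, in_y] + rg$shock
  }
  dimnames(F) <- list(cfg$ages, cal_years)
  F
}

scenario_baseline <- function(cfg) {
  bl <- cfg$baseline
  gompertz_makeham(cfg$ages, bl$c, bl$a, bl$b) +
    bl$infant * exp(-bl$infant_decay * cfg$ages)
}

# Cumulate an improvement field into a latent rate surface.
cumulate_rates <- function(m0, field) {
  if (any(field >= 100))
    abort_rmicast("config_error",
                  "shock drives improvement rates to >= 100 %")
  n <- ncol(field) + 1L
  M <- matrix(NA_real_, length(m0), n)
  M[, 1] <- m0
  for (t in 2:n) M[, t] <- M[, t - 1] * (1 - field[, t - 1] / 100)
  M
}

#' Generate a synthetic mortality scenario
#'
#' Builds the latent target surface by cumulating the regime-modified
#' improvement field from the baseline schedule, draws Poisson death counts
#' given exposures (zero counts are replaced by 0.5 so observed rates remain
#' positive), and generates reference populations from the lagged,
#' attenuated latent field with independent noise. Identical seeds give
#' identical output.
#'
#' @param cfg a [scenario_config()].
#' @return list with `target` (a [mortality_surface()] with deaths and
#'   exposures under Poisson noise), `references` (list of surfaces), and
#'   `truth` (latent `rates`, the improvement field `rho`, and the latent
#'   per-year `e0`).
#' @export
generate_scenario <- function(cfg) {
  if (!inherits(cfg, "scenario_config"))
    abort_rmicast("config_error", "cfg must be a scenario_config")
  set.seed(cfg$seed)
  A <- length(cfg$ages)
  E <- matrix(cfg$exposures, A, cfg$n_years)
  m0 <- scenario_baseline(cfg)
  trans_years <- cfg$years[-1]           # transitions end in years 2..n
  field <- scenario_field(cfg, trans_years)
  latent <- cumulate_rates(m0, field)
  dimnames(latent) <- list(cfg$ages, cfg$years)

  observe <- function(latent, population) {
    if (cfg$noise == "poisson") {
      deaths <- matrix(stats::rpois(length(latent), E * latent), A)
      deaths <- pmax(deaths, 0.5)        # keep observed rates positive
      mortality_surface(deaths / E, ages = cfg$ages, years = cfg$years,
                        deaths = deaths, exposures = E,
                        population = population, sex = "total")
    } else {
      mortality_surface(latent, ages = cfg$ages, years = cfg$years,
                        population = population, sex = "total")
    }
  }
  target <- observe(latent, "TGT")

  refs <- list()
  if (cfg$reference$n > 0) {
    ref_field <- cfg$reference$attenuation *
      scenario_field(cfg, trans_years + cfg$reference$lag)
    ref_latent <- cumulate_rates(m0 * cfg$reference$level_factor, ref_field)
    for (i in seq_len(cfg$reference$n))
      refs[[i]] <- observe(ref_latent, sprintf("REF%d", i))
  }
  list(target = target, references = refs,
       truth = list(rates = latent, rho = field,
                    e0 = stats::setNames(e0_matrix(latent), cfg$years)))
}
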