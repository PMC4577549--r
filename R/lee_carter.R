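# The Lee-Carter model: log m(x,t) = a(x) + b(x) k(t), with (b, k) the first
# singular pair of the centered log-rate matrix and k extrapolated as a
# random walk with drift. The classic comparator of any mortality forecast.

#' Fit the Lee-Carter model
#'
#' `a` is the per-age mean log rate; `(b, k)` is the first singular pair of
#' the centered log-rate matrix, rescaled to the standard identification
#' constraints sum(b) = 1 and sum(k) = 0. Normalizing `b` by its own sum
#' makes the fit invariant to the sign ambiguity of the SVD; for declining
#' mortality the resulting `k` decreases, i.e. drift <= 0. No second-stage
#' re-estimation of `k` is performed.
#'
#' @param s a [mortality_surface()] with at least 3 years and positive rates.
#' @return an object of class `lc_fit` with fields `a`, `b`, `k`, `drift`,
#'   `sigma_rw` (sd of random-walk innovations), `sigma_drift`
#'   (= `sigma_rw / sqrt(n_years - 1)`), `jumpoff_rates`, `years`, `ages`.
#' @export
fit_lc <- function(s) {
  validate_surface(s)
  if (length(s$years) < 3)
    abort_rmicast("insufficient_data_error", "Lee-Carter needs >= 3 years")
  L <- log(s$rates)
  a <- rowMeans(L)
  Z <- L - a
  if (sum(Z^2) < 1e-24)
    abort_rmicast("degenerate_fit_error",
                  "constant surface: centered log rates are rank 0")
  sv <- svd(Z, nu = 1, nv = 1)
  u <- sv$u[, 1]; v <- sv$v[, 1]; d1 <- sv$d[1]
  su <- sum(u)
  if (abs(su) < 1e-12)
    abort_rmicast("degenerate_fit_error",
                  "first singular vector sums to zero; b is unidentifiable")
  b <- u / su
  k <- su * d1 * v
  k <- k - mean(k)                      # enforce sum(k) = 0 exactly
  n <- length(k)
  drift <- (k[n] - k[1]) / (n - 1)
  resid <- diff(k) - drift
  sigma_rw <- sqrt(sum(resid^2) / max(n - 2, 1))
  structure(
    list(a = a, b = b, k = k, drift = drift, sigma_rw = sigma_rw,
         sigma_drift = sigma_rw / sqrt(n - 1),
         jumpoff_rates = s$rates[, ncol(s$rates)],
         ages = s$ages, years = s$years, population = s$population,
         sex = s$sex),
    class = "lc_fit")
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("<lc_fit> %s (%s), %d ages x %d years\n", x$population, x$sex,
              length(x$ages), length(x$years)))
  cat(sprintf("  drift %.4f, sigma_rw %.4f\n", x$drift, x$sigma_rw))
  invisible(x)
}

#' Forecast a Lee-Carter fit
#'
#' Simulates `k` forward as a random walk with drift. When
#' `include_drift_uncertainty` is set, the drift of each path is perturbed by
#' a normal draw with sd `sigma_drift`. Rates are reconstructed from the
#' last observed (jump-off) rates via `m(x,T+h) = m(x,T) exp(b(x) (k - k_T))`,
#' which keeps the jump-off year free of fitting bias.
#'
#' @param fit an `lc_fit`.
#' @param horizon number of years ahead (>= 1).
#' @param n_draws number of simulated paths (>= 1).
#' @param seed RNG seed.
#' @param include_drift_uncertainty logical (default `TRUE`).
#' @param a0,a_interior life-table conventions for the e0 quantiles.
#' @return a `forecast_result`; `extras$k_draws` holds the simulated k paths.
#' @export
forecast_lc <- function(fit, horizon, n_draws = 1000, seed = 1,
                        include_drift_uncertainty = TRUE,
                        a0 = 0.1, a_interior = 0.5) {
  if (horizon < 1 || n_draws < 1)
    abort_rmicast("domain_error", "horizon and n_draws must be >= 1")
  set.seed(seed)
  kT <- fit$k[length(fit$k)]
  drifts <- fit$drift +
    if (include_drift_uncertainty) stats::rnorm(n_draws, 0, fit$sigma_drift)
    else 0
  innov <- matrix(stats::rnorm(n_draws * horizon, 0, fit$sigma_rw),
                  n_draws, horizon)
  steps <- innov + drifts
  k_draws <- kT + t(apply(steps, 1, cumsum))
  if (horizon == 1) k_draws <- matrix(k_draws, n_draws, 1)

  A <- length(fit$ages)
  years <- max(fit$years) + seq_len(horizon)
  rate_draws <- array(NA_real_, c(n_draws, A, horizon))
  e0_draws <- matrix(NA_real_, n_draws, horizon)
  for (h in seq_len(horizon)) {
    # ages x draws rate matrix for horizon step h
    Mh <- fit$jumpoff_rates * exp(outer(fit$b, k_draws[, h] - kT))
    rate_draws[, , h] <- t(Mh)
    e0_draws[, h] <- e0_matrix(Mh, a0 = a0, a_interior = a_interior)
  }
  new_forecast_result(fit$population, years, e0_draws, rate_draws,
                      n_draws, seed, extras = list(k_draws = k_draws))
}
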