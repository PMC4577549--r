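# Coherent multi-population forecasting in the Li-Lee tradition: a common
# factor (B, K) shared by the group, per-population residual factors
# (b_i, k_i) with mean-reverting AR(1) dynamics, so forecasts for related
# populations cannot diverge without bound.

#' Fit the coherent (Li-Lee) multi-population model
#'
#' The group log surface is the weighted mean of the per-population log-rate
#' surfaces (equal weights by default, exposure-proportional on request).
#' `(B, K)` is its first singular pair under Lee-Carter constraints
#' (sum(B) = 1, sum(K) = 0) and `K` carries a random walk with drift.
#' Each population's residual `log m_i - a_i - B K` gets its own first
#' singular pair `(b_i, k_i)` and an AR(1) coefficient `phi_i` estimated by
#' least squares and clamped to `[0, 0.98]` — strictly below 1, which is what
#' makes the joint forecast coherent.
#'
#' @param surfaces list of >= 2 [mortality_surface()]s on identical grids.
#' @param weights optional nonnegative per-population weights; `"exposure"`
#'   uses total exposures when all surfaces carry them.
#' @return an object of class `li_lee_fit`.
#' @export
fit_li_lee <- function(surfaces, weights = NULL) {
  if (length(surfaces) < 2)
    abort_rmicast("domain_error", "coherent fit needs >= 2 populations")
  for (s in surfaces) validate_surface(s)
  ages <- surfaces[[1]]$ages; years <- surfaces[[1]]$years
  for (s in surfaces[-1]) {
    if (!identical(s$ages, ages) || !identical(s$years, years))
      abort_rmicast("alignment_error",
                    "all surfaces must share the same age/year grid")
  }
  npop <- length(surfaces)
  if (identical(weights, "exposure")) {
    tot <- vapply(surfaces, function(s) {
      if (is.null(s$exposures))
        abort_rmicast("domain_error", "exposure weighting needs exposures")
      sum(s$exposures)
    }, numeric(1))
    weights <- tot
  }
  if (is.null(weights)) weights <- rep(1, npop)
  if (any(weights < 0) || sum(weights) == 0)
    abort_rmicast("domain_error", "weights must be nonnegative, not all zero")
  w <- weights / sum(weights)

  logs <- lapply(surfaces, function(s) log(s$rates))
  group <- Reduce(`+`, Map(`*`, logs, w))
  gfit <- fit_lc(mortality_surface(exp(group), ages = ages, years = years,
                                   population = "group", sex = surfaces[[1]]$sex))
  B <- gfit$b; K <- gfit$k
  common <- outer(B, K)

  pops <- vector("list", npop)
  for (i in seq_len(npop)) {
    Li <- logs[[i]]
    ai <- rowMeans(Li)
    Ri <- Li - ai - common
    if (sum(Ri^2) < 1e-20) {
      bi <- rep(1 / length(ages), length(ages))
      ki <- rep(0, length(years))
    } else {
      sv <- svd(Ri, nu = 1, nv = 1)
      su <- sum(sv$u[, 1])
      if (abs(su) < 1e-12) {           # unidentifiable residual: treat as noise
        bi <- rep(1 / length(ages), length(ages))
        ki <- rep(0, length(years))
      } else {
        bi <- sv$u[, 1] / su
        ki <- su * sv$d[1] * sv$v[, 1]
        ki <- ki - mean(ki)
      }
    }
    den <- sum(ki[-length(ki)]^2)
    phi <- if (den > 0) sum(ki[-1] * ki[-length(ki)]) / den else 0
    phi <- min(max(phi, 0), 0.98)
    res <- ki[-1] - phi * ki[-length(ki)]
    sigma <- sqrt(sum(res^2) / max(length(res) - 1, 1))
    pops[[i]] <- list(
      population = surfaces[[i]]$population, a = ai, b = bi, k = ki,
      phi = phi, sigma = sigma,
      jumpoff_rates = surfaces[[i]]$rates[, length(years)])
  }
  names(pops) <- vapply(pops, `[[`, "", "population")
  structure(
    list(populations = names(pops), B = B, K = K, K_drift = gfit$drift,
         K_sigma = gfit$sigma_rw, K_sigma_drift = gfit$sigma_drift,
         pop = pops, ages = ages, years = years, weights = w,
         sex = surfaces[[1]]$sex),
    class = "li_lee_fit")
}

#' @export
print.li_lee_fit <- function(x, ...) {
  cat(sprintf("<li_lee_fit> %d populations: %s\n", length(x$pop),
              paste(x$populations, collapse = ", ")))
  cat(sprintf("  K drift %.4f, sigma %.4f; phi: %s\n", x$K_drift, x$K_sigma,
              paste(sprintf("%.2f", vapply(x$pop, `[[`, 0, "phi")),
                    collapse = ", ")))
  invisible(x)
}

#' Forecast a coherent Li-Lee fit
#'
#' `K` is simulated as a random walk with drift; each `k_i` as a zero-mean
#' AR(1) with coefficient `phi_i`, so population deviations from the common
#' trend decay toward zero. Per-population rates are launched from the
#' jump-off rates via `exp(B dK + b_i dk_i)`.
#'
#' @param fit a `li_lee_fit`.
#' @param horizon,n_draws,seed as in [forecast_lc()].
#' @param include_drift_uncertainty perturb the drift of `K` per path.
#' @param a0,a_interior life-table conventions for the e0 quantiles.
#' @return named list of `forecast_result`, one per population;
#'   each carries `extras$k_draws` (its AR(1) paths) and `extras$K_draws`.
#' @export
forecast_li_lee <- function(fit, horizon, n_draws = 1000, seed = 1,
                            include_drift_uncertainty = TRUE,
                            a0 = 0.1, a_interior = 0.5) {
  if (horizon < 1 || n_draws < 1)
    abort_rmicast("domain_error", "horizon and n_draws must be >= 1")
  set.seed(seed)
  KT <- fit$K[length(fit$K)]
  drifts <- fit$K_drift +
    if (include_drift_uncertainty) stats::rnorm(n_draws, 0, fit$K_sigma_drift)
    else 0
  steps <- matrix(stats::rnorm(n_draws * horizon, 0, fit$K_sigma),
                  n_draws, horizon) + drifts
  K_draws <- KT + t(apply(steps, 1, cumsum))
  if (horizon == 1) K_draws <- matrix(K_draws, n_draws, 1)

  years <- max(fit$years) + seq_len(horizon)
  A <- length(fit$ages)
  out <- vector("list", length(fit$pop))
  names(out) <- fit$populations
  for (i in seq_along(fit$pop)) {
    p <- fit$pop[[i]]
    kT <- p$k[length(p$k)]
    k_draws <- matrix(NA_real_, n_draws, horizon)
    prev <- rep(kT, n_draws)
    for (h in seq_len(horizon)) {
      prev <- p$phi * prev + stats::rnorm(n_draws, 0, p$sigma)
      k_draws[, h] <- prev
    }
    rate_draws <- array(NA_real_, c(n_draws, A, horizon))
    e0_draws <- matrix(NA_real_, n_draws, horizon)
    for (h in seq_len(horizon)) {
      Mh <- p$jumpoff_rates *
        exp(outer(fit$B, K_draws[, h] - KT) + outer(p$b, k_draws[, h] - kT))
      rate_draws[, , h] <- t(Mh)
      e0_draws[, h] <- e0_matrix(Mh, a0 = a0, a_interior = a_interior)
    }
    out[[i]] <- new_forecast_result(
      p$population, years, e0_draws, rate_draws, n_draws, seed,
      extras = list(k_draws = k_draws, K_draws = K_draws))
  }
  out
}
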