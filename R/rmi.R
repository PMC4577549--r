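# Probabilistic forecasting of rates of mortality improvement (RMI).
#
# The model works in rho-space: for each age x the smoothed improvement
# surface is described by a linear time trend
#     rho(x, t) = alpha_x + beta_x (t - t_mid) + eps,  eps ~ N(0, sigma_x^2),
# fitted jointly across ages with an order-2 smoothness penalty on the alpha
# and beta age profiles. A positive beta above the current improvement peak
# and a negative beta below it is exactly how a dynamic shift of survival
# improvements toward older ages expresses itself, so the linear trend can
# extrapolate that shift. Optionally the extrapolated target trend is
# blended toward the pooled trend of reference populations with a weight
# that grows with the forecast horizon, w(h) = w_max (1 - exp(-h / tau)):
# trend changes seen earlier in the references increasingly inform the
# long-run forecast. Parameter uncertainty comes from a residual bootstrap
# over years (joint across ages, preserving the cross-age correlation of
# period shocks).

#' Configuration for the improvement-rate forecaster
#'
#' All tunable constants of [fit_rmi()] / [forecast_rmi()] live here and are
#' echoed into the fit and forecast objects.
#'
#' @param w_max maximal blending weight toward the reference trend (0 =
#'   references ignored; default 0.5).
#' @param tau e-folding horizon, in years, of the blending weight
#'   `w(h) = w_max (1 - exp(-h/tau))` (default 10; `tau <= 0` means the full
#'   weight applies from the first forecast year).
#' @param clamp two-sided bound, in percent, applied to simulated
#'   improvement rates (default `c(-25, 25)`).
#' @param lambda_trend order-2 age-smoothness penalty on the alpha and beta
#'   profiles (default 10).
#' @param lambda_age,lambda_year,knot_spacing passed to [smooth_surface()]
#'   for the pre-smoothing of the rate surface (defaults 10, 10, 5).
#' @param smooth logical; smooth the surface before computing improvement
#'   rates (default `TRUE`). Disable only for exactness checks.
#' @param block_length moving-block length (years) of the residual
#'   bootstrap; `NULL` (default) uses `2 * knot_spacing`, the correlation
#'   range the time smoother induces in the residuals.
#' @param n_draws number of bootstrap parameter draws stored in the fit.
#' @param a0,a_interior life-table conventions used for e0 summaries.
#' @return a list of class `rmi_config`.
#' @export
rmi_config <- function(w_max = 0.5, tau = 10, clamp = c(-25, 25),
                       lambda_trend = 10, lambda_age = 10, lambda_year = 10,
                       knot_spacing = 5, smooth = TRUE, block_length = NULL,
                       n_draws = 500, a0 = 0.1, a_interior = 0.5) {
  if (w_max < 0 || w_max > 1)
    abort_rmicast("domain_error", "w_max must lie in [0, 1]")
  if (is.null(block_length)) block_length <- 2 * knot_spacing
  structure(list(w_max = w_max, tau = tau, clamp = sort(clamp),
                 lambda_trend = lambda_trend, lambda_age = lambda_age,
                 lambda_year = lambda_year, knot_spacing = knot_spacing,
                 smooth = smooth, block_length = block_length,
                 n_draws = n_draws,
                 a0 = a0, a_interior = a_interior),
            class = "rmi_config")
}

# Penalized linear trend fit in rho-space. Because the time regressor is
# centered, the alpha and beta systems decouple and each solves a ridge-type
# equation with the order-2 age penalty; closed form, reused by the
# bootstrap with fixed solve operators.
rmi_trend_fit <- function(rho, years, lambda) {
  A <- nrow(rho); nT <- ncol(rho)
  t_mid <- mean(years)
  u <- years - t_mid
  Su2 <- sum(u^2)
  P <- diff_penalty(A, 2)
  Ma <- solve(diag(A) + (lambda / nT) * P)
  Mb <- solve(diag(A) + (lambda / Su2) * P)
  alpha <- as.vector(Ma %*% rowMeans(rho))
  beta <- as.vector(Mb %*% (rho %*% u)) / Su2
  fitted <- alpha + outer(beta, u)
  resid <- rho - fitted
  sigma <- sqrt(rowSums(resid^2) / max(nT - 2, 1))
  list(alpha = alpha, beta = beta, sigma = sigma, fitted = fitted,
       resid = resid, t_mid = t_mid, u = u, Su2 = Su2, Ma = Ma, Mb = Mb)
}

# Joint residual bootstrap over years: resample year columns of the residual
# matrix (jointly across ages) and refit via the precomputed operators.
# Because the time smoother leaves residuals serially correlated over roughly
# the support of one B-spline (about twice the knot spacing), columns are
# resampled in moving blocks of that length; an iid column bootstrap would
# understate the trend uncertainty by about sqrt(block length).
rmi_trend_boot <- function(tf, n_draws, block_length = 10) {
  A <- length(tf$alpha); nT <- length(tf$u)
  L <- max(1L, min(as.integer(block_length), nT))
  alpha_d <- matrix(NA_real_, n_draws, A)
  beta_d <- matrix(NA_real_, n_draws, A)
  base_a <- rowMeans(tf$fitted)
  base_b <- as.vector(tf$fitted %*% tf$u)
  n_blocks <- ceiling(nT / L)
  # standard finite-sample correction: block means understate the variance
  # of the full-sample mean by a factor (1 - L/n)
  infl <- 1 / sqrt(max(1 - L / nT, 0.25))
  for (d in seq_len(n_draws)) {
    starts <- sample.int(nT - L + 1L, n_blocks, replace = TRUE)
    cols <- as.vector(outer(0:(L - 1L), starts, `+`))[seq_len(nT)]
    E <- infl * tf$resid[, cols, drop = FALSE]
    alpha_d[d, ] <- tf$Ma %*% (base_a + rowMeans(E))
    beta_d[d, ] <- (tf$Mb %*% (base_b + E %*% tf$u)) / tf$Su2
  }
  list(alpha = alpha_d, beta = beta_d)
}

#' Fit the improvement-rate forecasting model
#'
#' Smooths the target surface (Poisson P-spline when counts are present, log
#' least squares otherwise), computes rates of mortality improvement, and
#' fits per-age linear time trends with an age-smoothness penalty. When
#' reference surfaces are supplied, their improvement surfaces are pooled
#' with equal weights and receive the same trend fit, yielding the reference
#' trend that [forecast_rmi()] can blend in.
#'
#' @param target a [mortality_surface()] with at least 10 years.
#' @param references list (possibly empty) of `mortality_surface`s covering
#'   the same ages and years as `target`.
#' @param config an [rmi_config()].
#' @param seed RNG seed for the bootstrap draws.
#' @return an object of class `rmi_fit` with the per-age `alpha`, `beta`,
#'   `sigma` (all in percent), `reference_alpha`/`reference_beta` (when
#'   references were given), bootstrap `draws`, jump-off rates, and the
#'   configuration echo.
#' @export
fit_rmi <- function(target, references = list(), config = rmi_config(),
                    seed = 1) {
  validate_surface(target)
  if (length(target$years) < 10)
    abort_rmicast("insufficient_data_error",
                  "improvement-rate model needs a base period of >= 10 years")
  for (r in references) {
    validate_surface(r)
    if (!identical(r$ages, target$ages) || !identical(r$years, target$years))
      abort_rmicast("alignment_error",
                    "reference surfaces must share the target's age/year grid")
  }
  prep <- function(s, cov = FALSE) {
    ss <- if (config$smooth)
      smooth_surface(s, config$lambda_age, config$lambda_year,
                     config$knot_spacing, last_year_cov = cov) else s
    list(rho = improvement_rates(ss), smoothed = ss)
  }
  prep_t <- prep(target, cov = config$smooth)
  rho_t <- prep_t$rho
  jump_chol <- NULL
  if (config$smooth) {
    V <- attr(prep_t$smoothed, "last_year_logcov")
    jump_chol <- chol(V + diag(1e-12, nrow(V)))
  }
  tf <- rmi_trend_fit(rho_t$rho, rho_t$years, config$lambda_trend)
  set.seed(seed)
  draws <- rmi_trend_boot(tf, config$n_draws, config$block_length)

  ref <- NULL
  if (length(references) > 0 && config$w_max > 0) {
    rhos <- lapply(references, function(r) prep(r)$rho$rho)
    pooled <- Reduce(`+`, rhos) / length(rhos)
    rf <- rmi_trend_fit(pooled, rho_t$years, config$lambda_trend)
    set.seed(seed + 1000003L)
    rdraws <- rmi_trend_boot(rf, config$n_draws, config$block_length)
    ref <- list(alpha = rf$alpha, beta = rf$beta, sigma = rf$sigma,
                draws = rdraws,
                populations = vapply(references, `[[`, "", "population"))
  }
  structure(
    list(ages = target$ages, base_years = target$years,
         rho_years = rho_t$years, t_mid = tf$t_mid,
         alpha = tf$alpha, beta = tf$beta, sigma = tf$sigma,
         resid = tf$resid, draws = draws,
         reference_alpha = if (is.null(ref)) NULL else ref$alpha,
         reference_beta = if (is.null(ref)) NULL else ref$beta,
         reference = ref,
         # launch from the fitted surface: the raw last-year column carries
         # Poisson noise straight into every forecast year
         jumpoff_rates = prep_t$smoothed$rates[, length(target$years)],
         jumpoff_rates_raw = target$rates[, length(target$years)],
         jumpoff_logchol = jump_chol,
         jumpoff_year = max(target$years),
         population = target$population, sex = target$sex,
         config = config, seed = seed),
    class = "rmi_fit")
}

#' @export
print.rmi_fit <- function(x, ...) {
  cat(sprintf("<rmi_fit> %s (%s), base %d-%d\n", x$population, x$sex,
              min(x$base_years), max(x$base_years)))
  cat(sprintf("  mean alpha %.2f%%, mean beta %.3f%%/yr, %d draws%s\n",
              mean(x$alpha), mean(x$beta), nrow(x$draws$alpha),
              if (is.null(x$reference)) "" else
                sprintf(", references: %s",
                        paste(x$reference$populations, collapse = "+"))))
  invisible(x)
}

#' Forecast from an improvement-rate fit
#'
#' For each parameter draw and horizon step `h`, the target trend
#' `alpha + beta (T + h - t_mid)` is blended with the reference trend using
#' `w(h) = w_max (1 - exp(-h/tau))`, per-age Gaussian residual noise with sd
#' `sigma_x` is added, the result is clamped to the configured bounds, and
#' rates are cumulated from the jump-off rates:
#' `m(x, T+h) = m(x, T) prod_{j<=h} (1 - rho_hat(x, j)/100)`. A warning of
#' class `clamp_saturation` is emitted when more than 5 % of the simulated
#' cells hit the clamp.
#'
#' @param fit an `rmi_fit`.
#' @param horizon number of years ahead (>= 1).
#' @param n_draws number of simulated trajectories (default: the number of
#'   parameter draws stored in the fit).
#' @param seed RNG seed.
#' @param jumpoff optional replacement jump-off rate vector.
#' @return a `forecast_result`; `extras$rho_median` holds the median
#'   simulated improvement surface (ages x horizon) and `extras$w` the
#'   blending-weight path.
#' @export
forecast_rmi <- function(fit, horizon, n_draws = NULL, seed = 1,
                         jumpoff = NULL) {
  if (horizon < 1)
    abort_rmicast("domain_error", "horizon must be >= 1")
  cfg <- fit$config
  if (is.null(jumpoff)) jumpoff <- fit$jumpoff_rates
  n_avail <- nrow(fit$draws$alpha)
  if (is.null(n_draws)) n_draws <- n_avail
  if (n_draws < 1)
    abort_rmicast("domain_error", "n_draws must be >= 1")
  set.seed(seed)
  idx <- if (n_draws == n_avail) seq_len(n_avail)
         else sample.int(n_avail, n_draws, replace = TRUE)

  A <- length(fit$ages); H <- as.integer(horizon)
  tt <- fit$jumpoff_year + seq_len(H) - fit$t_mid
  w <- if (cfg$tau <= 0) rep(cfg$w_max, H)
       else cfg$w_max * (1 - exp(-seq_len(H) / cfg$tau))
  has_ref <- !is.null(fit$reference)
  years <- fit$jumpoff_year + seq_len(H)

  # per-draw launch-point perturbation: the jump-off column is itself an
  # estimate; its log-scale covariance comes from the surface smoother
  use_jc <- !is.null(fit$jumpoff_logchol) && identical(jumpoff,
                                                       fit$jumpoff_rates)
  jump_pert <- if (use_jc)
    matrix(stats::rnorm(n_draws * A), n_draws, A) %*% fit$jumpoff_logchol
  else matrix(0, n_draws, A)

  rho_draws <- array(NA_real_, c(n_draws, A, H))
  big_logm <- matrix(NA_real_, A, H * n_draws)
  n_sat <- 0
  for (d in seq_len(n_draws)) {
    i <- idx[d]
    g <- fit$draws$alpha[i, ] + outer(fit$draws$beta[i, ], tt)
    if (has_ref) {
      gr <- fit$reference$draws$alpha[i, ] +
        outer(fit$reference$draws$beta[i, ], tt)
      g <- g * rep(1 - w, each = A) + gr * rep(w, each = A)
    }
    # future period shocks: resampled residual columns, keeping the
    # cross-age correlation of period effects (marginal sd is sigma_x);
    # iid-per-age noise would diversify away in e0 and understate intervals
    g <- g + fit$resid[, sample.int(ncol(fit$resid), H, replace = TRUE),
                       drop = FALSE]
    sat <- g < cfg$clamp[1] | g > cfg$clamp[2]
    n_sat <- n_sat + sum(sat)
    g <- pmin(pmax(g, cfg$clamp[1]), cfg$clamp[2])
    rho_draws[d, , ] <- g
    cum <- if (H == 1) log1p(-g / 100)
           else t(apply(log1p(-g / 100), 1, cumsum))
    big_logm[, (d - 1L) * H + seq_len(H)] <-
      log(jumpoff) + jump_pert[d, ] + cum
  }
  if (n_sat / (n_draws * A * H) > 0.05)
    warn_rmicast("clamp_saturation", sprintf(
      "improvement-rate clamp hit in %.1f%% of simulated cells",
      100 * n_sat / (n_draws * A * H)))

  e0_all <- e0_matrix(exp(big_logm), a0 = cfg$a0, a_interior = cfg$a_interior)
  e0_draws <- matrix(e0_all, n_draws, H, byrow = TRUE)
  rate_draws <- aperm(array(exp(big_logm), c(A, H, n_draws)), c(3, 1, 2))
  rho_median <- apply(rho_draws, c(2, 3), stats::median)
  dimnames(rho_median) <- list(fit$ages, years)
  new_forecast_result(fit$population, years, e0_draws, rate_draws,
                      n_draws, seed,
                      extras = list(rho_median = rho_median, w = w))
}
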