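# exact rho-space fixture: improvement rates exactly linear in time per age
linear_rho_surface <- function(alpha, beta, n_years = 20, start_year = 1990,
                               m0 = NULL) {
  A <- length(alpha)
  years <- start_year + 0:(n_years - 1)
  t_mid <- mean(years[-1])
  if (is.null(m0)) m0 <- exp(seq(-6, -1, length.out = A))
  M <- matrix(NA_real_, A, n_years); M[, 1] <- m0
  for (t in 2:n_years) {
    rho <- alpha + beta * (years[t] - t_mid)
    M[, t] <- M[, t - 1] * (1 - rho / 100)
  }
  mortality_surface(M, 0:(A - 1), years, population = "LIN")
}

test_that("noise-free linear improvement trends are recovered exactly", {
  alpha <- seq(1, 3, length.out = 12)
  beta <- seq(-0.05, 0.08, length.out = 12)
  s <- linear_rho_surface(alpha, beta)
  cfg <- rmi_config(smooth = FALSE, lambda_trend = 0, n_draws = 20)
  fit <- fit_rmi(s, config = cfg)
  expect_lt(max(abs(fit$alpha - alpha)), 1e-8)
  expect_lt(max(abs(fit$beta - beta)), 1e-8)
  expect_lt(max(fit$sigma), 1e-8)
  # draw means sit on the point estimates when residuals vanish
  expect_lt(max(abs(colMeans(fit$draws$alpha) - alpha)), 1e-8)
})

test_that("w_max = 0 makes references irrelevant", {
  s <- linear_rho_surface(rep(2, 8), rep(0.02, 8))
  r <- linear_rho_surface(rep(4, 8), rep(-0.01, 8))
  r$population <- "REF"
  cfg <- rmi_config(w_max = 0, smooth = FALSE, n_draws = 30)
  f0 <- fit_rmi(s, config = cfg, seed = 9)
  f1 <- fit_rmi(s, references = list(r), config = cfg, seed = 9)
  expect_null(f1$reference)
  expect_equal(f0$alpha, f1$alpha)
  expect_equal(f0$draws, f1$draws)
  fc0 <- forecast_rmi(f0, 5, seed = 2)
  fc1 <- forecast_rmi(f1, 5, seed = 2)
  expect_equal(fc0$e0_quantiles, fc1$e0_quantiles)
})

test_that("a huge age penalty shrinks alpha and beta onto age-linear profiles", {
  # small grid so the stated penalty dominates the data term to 1e-6
  A <- 10
  alpha <- 2 + 0.1 * sin((0:(A - 1)) / 2)
  beta <- 0.02 + 0.005 * cos((0:(A - 1)) / 2)
  s <- linear_rho_surface(alpha, beta, n_years = 13)
  cfg <- rmi_config(smooth = FALSE, lambda_trend = 1e8, n_draws = 5)
  fit <- fit_rmi(s, config = cfg)
  # independent least-squares oracle: per-age OLS estimates projected onto
  # the best age-linear profile
  rho <- improvement_rates(s)$rho
  u <- as.numeric(colnames(rho)) - mean(as.numeric(colnames(rho)))
  a_ols <- rowMeans(rho)
  b_ols <- as.vector(rho %*% u) / sum(u^2)
  x <- 0:(A - 1)
  lin <- function(y) stats::fitted(stats::lm(y ~ x))
  expect_lt(max(abs(fit$alpha - lin(a_ols))), 1e-6)
  expect_lt(max(abs(fit$beta - lin(b_ols))), 1e-6)
})

test_that("geometric cumulation is exact in the deterministic limit", {
  c0 <- 1.8
  s <- linear_rho_surface(rep(c0, 10), rep(0, 10))
  cfg <- rmi_config(w_max = 0, smooth = FALSE, n_draws = 1)
  fit <- fit_rmi(s, config = cfg)
  fc <- forecast_rmi(fit, 6, n_draws = 1, seed = 1)
  for (h in c(1, 3, 6))
    expect_equal(unname(fc$rate_quantiles["0.5", , h]),
                 unname(fit$jumpoff_rates * (1 - c0 / 100)^h),
                 tolerance = 1e-10)
})

test_that("full blending with tau -> 0 follows the reference trend for all h", {
  s <- linear_rho_surface(rep(1, 10), rep(0, 10))
  r <- linear_rho_surface(rep(3, 10), rep(0, 10))
  cfg <- rmi_config(w_max = 1, tau = 0, smooth = FALSE, n_draws = 1)
  fit <- fit_rmi(s, references = list(r), config = cfg)
  fit$resid[] <- 0                      # deterministic limit
  fit$reference$draws$alpha[] <- 3; fit$reference$draws$beta[] <- 0
  fit$draws$alpha[] <- 1; fit$draws$beta[] <- 0
  fc <- forecast_rmi(fit, 5, n_draws = 1, seed = 1)
  expect_equal(unname(fc$extras$rho_median),
               matrix(3, 10, 5), tolerance = 1e-10)
})

test_that("e0 quantiles are monotone across levels for every year", {
  scen <- generate_scenario(scenario_config("regular", seed = 31,
                                            ages = 0:80, n_years = 30))
  base <- subset_surface(scen$target, year_range = c(1950, 1974))
  fit <- fit_rmi(base, config = rmi_config(n_draws = 100), seed = 1)
  fc <- forecast_rmi(fit, 8, n_draws = 500, seed = 2)
  for (j in seq_along(fc$years))
    expect_false(is.unsorted(fc$e0_quantiles[, j]))
})

test_that("clamp saturation raises a typed warning", {
  s <- linear_rho_surface(rep(40, 6), rep(0, 6))  # trend beyond the clamp
  cfg <- rmi_config(w_max = 0, smooth = FALSE, n_draws = 10)
  fit <- fit_rmi(s, config = cfg)
  expect_warning(forecast_rmi(fit, 4, seed = 1), class = "clamp_saturation")
})

test_that("fit_rmi validates base period and reference alignment", {
  s <- linear_rho_surface(rep(2, 6), rep(0, 6), n_years = 8)
  expect_error(fit_rmi(s, config = rmi_config(smooth = FALSE)),
               class = "insufficient_data_error")
  s2 <- linear_rho_surface(rep(2, 6), rep(0, 6), n_years = 20)
  r2 <- linear_rho_surface(rep(2, 6), rep(0, 6), n_years = 20,
                           start_year = 1991)
  expect_error(fit_rmi(s2, references = list(r2),
                       config = rmi_config(smooth = FALSE)),
               class = "alignment_error")
})

test_that("stagnation-recovery: an informative reference lifts the forecast", {
  scen <- generate_scenario(scenario_config("stagnation-recovery", seed = 77))
  base <- subset_surface(scen$target, year_range = c(1965, 1990))
  refs <- lapply(scen$references, subset_surface, year_range = c(1965, 1990))
  f_ref <- fit_rmi(base, refs, rmi_config(w_max = 0.5, n_draws = 150), seed = 3)
  f_solo <- fit_rmi(base, config = rmi_config(w_max = 0, n_draws = 150), seed = 3)
  e_ref <- median_e0(forecast_rmi(f_ref, 15, seed = 4))
  e_solo <- median_e0(forecast_rmi(f_solo, 15, seed = 4))
  expect_gt(e_ref[15], e_solo[15])
})
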