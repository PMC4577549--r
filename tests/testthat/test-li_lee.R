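# two coupled populations whose improvement levels differ, built in
# rho-space so the divergence under independent forecasts is known
divergent_pair <- function(n_ages = 40, n_years = 30, rho1 = 2.2, rho2 = 0.8,
                           noise = 0.01, seed = 42) {
  set.seed(seed)
  ages <- 0:(n_ages - 1); years <- 1970 + 0:(n_years - 1)
  m0 <- exp(seq(-5.5, -0.5, length.out = n_ages))
  mk <- function(rho) {
    M <- matrix(NA_real_, n_ages, n_years); M[, 1] <- m0
    for (t in 2:n_years) M[, t] <- M[, t - 1] * (1 - rho / 100)
    M * exp(matrix(stats::rnorm(length(M), 0, noise), n_ages))
  }
  list(a = mortality_surface(mk(rho1), ages, years, population = "A"),
       b = mortality_surface(mk(rho2), ages, years, population = "B"))
}

test_that("identical exact populations degenerate to the single-population fit", {
  fx <- lc_surface(n_ages = 25, n_years = 20)
  fit <- fit_li_lee(list(fx$surface, fx$surface))
  single <- fit_lc(fx$surface)
  expect_lt(max(abs(fit$B - single$b)), 1e-8)
  expect_lt(max(abs(fit$K - single$k)), 1e-8)
  for (p in fit$pop) expect_lt(max(abs(p$k)), 1e-8)
})

test_that("the common factor equals Lee-Carter on the weighted-mean log surface", {
  pair <- divergent_pair()
  w <- c(0.3, 0.7)
  fit <- fit_li_lee(list(pair$a, pair$b), weights = w)
  avg <- mortality_surface(
    exp(0.3 * log(pair$a$rates) + 0.7 * log(pair$b$rates)),
    pair$a$ages, pair$a$years)
  ref <- fit_lc(avg)
  expect_equal(fit$B, ref$b, tolerance = 1e-10)
  expect_equal(fit$K, ref$k, tolerance = 1e-10)
  # constraints for common and population factors
  expect_equal(sum(fit$B), 1, tolerance = 1e-12)
  expect_equal(sum(fit$K), 0, tolerance = 1e-12)
  for (p in fit$pop) {
    expect_equal(sum(p$b), 1, tolerance = 1e-10)
    expect_equal(sum(p$k), 0, tolerance = 1e-10)
    expect_true(p$phi >= 0 && p$phi <= 0.98)
  }
})

test_that("fit_li_lee rejects bad input", {
  pair <- divergent_pair()
  expect_error(fit_li_lee(list(pair$a)), class = "domain_error")
  shifted <- subset_surface(pair$b, year_range = c(1971, 1999))
  expect_error(fit_li_lee(list(pair$a, shifted)), class = "alignment_error")
})

test_that("phi = sigma = 0 collapses population dynamics onto the common factor", {
  pair <- divergent_pair()
  fit <- fit_li_lee(list(pair$a, pair$b))
  for (nm in names(fit$pop)) {
    fit$pop[[nm]]$phi <- 0; fit$pop[[nm]]$sigma <- 0
  }
  fc <- forecast_li_lee(fit, horizon = 6, n_draws = 1, seed = 1,
                        include_drift_uncertainty = FALSE)
  fit$K_sigma <- 0   # not needed: single draw, but keep K stochastic-free
  lrA <- log(fc$A$rate_quantiles["0.5", , ])
  for (h in 2:6) {
    dK <- fc$A$extras$K_draws[1, h] - fc$A$extras$K_draws[1, h - 1]
    expect_equal(lrA[, h] - lrA[, h - 1], fit$B * dK, tolerance = 1e-8)
  }
})

test_that("AR(1) median follows phi^h k_T", {
  pair <- divergent_pair()
  fit <- fit_li_lee(list(pair$a, pair$b))
  p <- fit$pop$A
  fc <- forecast_li_lee(fit, horizon = 12, n_draws = 2000, seed = 5)
  kT <- p$k[length(p$k)]
  for (h in c(1, 6, 12)) {
    draws <- fc$A$extras$k_draws[, h]
    mcse <- stats::sd(draws) / sqrt(2000) * sqrt(pi / 2)
    expect_lt(abs(stats::median(draws) - p$phi^h * kT), 3 * mcse + 1e-12)
  }
})

test_that("coherent forecasts keep diverging populations together", {
  pair <- divergent_pair()
  h <- 50
  fc1 <- forecast_lc(fit_lc(pair$a), h, n_draws = 400, seed = 1)
  fc2 <- forecast_lc(fit_lc(pair$b), h, n_draws = 400, seed = 2)
  gap_ind <- abs(median_e0(fc1)[h] - median_e0(fc2)[h])
  fit <- fit_li_lee(list(pair$a, pair$b))
  fcc <- forecast_li_lee(fit, h, n_draws = 400, seed = 3)
  gap_coh <- abs(median_e0(fcc$A)[h] - median_e0(fcc$B)[h])
  expect_lt(gap_coh, gap_ind)
  # deterministic coherence: with sigma_i = 0 the median log-rate gap at
  # long horizons is bounded by the jump-off gap plus the decaying k terms
  for (nm in names(fit$pop)) fit$pop[[nm]]$sigma <- 0
  fcd <- forecast_li_lee(fit, 60, n_draws = 1, seed = 4,
                         include_drift_uncertainty = FALSE)
  gap_log <- log(fcd$A$rate_quantiles["0.5", , 60]) -
             log(fcd$B$rate_quantiles["0.5", , 60])
  jump_gap <- log(fit$pop$A$jumpoff_rates) - log(fit$pop$B$jumpoff_rates)
  resid_k <- abs(fit$pop$A$b * fit$pop$A$k[30] * fit$pop$A$phi^60) +
             abs(fit$pop$B$b * fit$pop$B$k[30] * fit$pop$B$phi^60) +
             abs(fit$pop$A$b * fit$pop$A$k[30]) +
             abs(fit$pop$B$b * fit$pop$B$k[30])
  expect_true(all(abs(gap_log - jump_gap) <= resid_k + 1e-8))
})
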