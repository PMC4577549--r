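test_that("forecast errors carry the overestimate-positive sign convention", {
  obs <- c(`1991` = 70, `1992` = 70.5, `1993` = 71)
  expect_equal(forecast_errors(obs, obs), c(`1991` = 0, `1992` = 0, `1993` = 0))
  expect_equal(unname(forecast_errors(obs + 0.5, obs)), rep(0.5, 3))
  expect_equal(forecast_errors(obs + 0.3, obs),
               -forecast_errors(obs, obs + 0.3))
  expect_error(forecast_errors(obs, obs[1:2]), class = "alignment_error")
  obs2 <- obs; names(obs2) <- 1992:1994
  expect_error(forecast_errors(obs, obs2), class = "alignment_error")
})

test_that("mae is the mean absolute error and respects its bounds", {
  expect_equal(mae(c(0.5, -0.5, 1.0)), 2 / 3, tolerance = 1e-12)
  expect_identical(mae(rep(0, 5)), 0)
  e <- c(0.2, -1.3, 0.7, 0.1)
  expect_equal(mae(e), mae(-e))
  expect_equal(mae(e), mae(abs(e)))
  expect_lte(abs(mean(e)), mae(e))          # Jensen
  expect_lte(mae(e), max(abs(e)))
  expect_error(mae(numeric(0)), class = "domain_error")
})

test_that("the retrospective harness scores exactly the held-out years", {
  scen <- generate_scenario(scenario_config("crisis-recovery", seed = 3))
  stub <- function(base_surface, refs, horizon_years, n_draws, seed) {
    # perfect-foresight oracle: returns the observed e0
    e0_series(subset_surface(scen$target,
                             year_range = range(horizon_years)))
  }
  rep_ <- run_retrospective(scen$target, base = c(1965, 1990),
                            horizon_end = 2009,
                            models = list(oracle = stub, lee_carter = "lee_carter"),
                            n_draws = 50, seed = 1)
  expect_identical(rep_$horizon_years, 1991:2009)
  expect_identical(length(rep_$horizon_years), 19L)
  expect_identical(rep_$models$oracle$status, "ok")
  expect_equal(rep_$models$oracle$mae, 0, tolerance = 1e-12)
  expect_identical(length(rep_$models$lee_carter$fe), 19L)
  # internal consistency: stored MAE equals mae(fe) recomputed
  expect_equal(rep_$models$lee_carter$mae,
               mae(rep_$models$lee_carter$fe), tolerance = 1e-12)
  # sensitivity run echoes its own base period
  rep75 <- run_retrospective(scen$target, base = c(1975, 1990),
                             horizon_end = 2009, models = "lee_carter",
                             n_draws = 50, seed = 1)
  expect_identical(rep75$base, c(1975, 1990))
})

test_that("model failures become error-status rows without aborting the run", {
  scen <- generate_scenario(scenario_config("regular", seed = 5,
                                            ages = 0:60, n_years = 40))
  boom <- function(...) rmicast:::abort_rmicast("degenerate_fit_error", "boom")
  rep_ <- run_retrospective(scen$target, base = c(1950, 1979),
                            horizon_end = 1989,
                            models = list(bad = boom, lee_carter = "lee_carter"),
                            n_draws = 50, seed = 1)
  expect_identical(rep_$models$bad$status, "error:degenerate_fit_error")
  expect_true(is.na(rep_$models$bad$mae))
  expect_identical(rep_$models$lee_carter$status, "ok")
  # li_lee without references is a typed failure, not an abort
  rep2 <- run_retrospective(scen$target, base = c(1950, 1979),
                            horizon_end = 1989, models = "li_lee",
                            n_draws = 50, seed = 1)
  expect_match(rep2$models$li_lee$status, "^error:")
  tabs <- report_tables(rep_)
  expect_identical(nrow(tabs$mae), 2L)
  expect_true(all(tabs$errors$model == "lee_carter"))
})

test_that("design errors are rejected up front", {
  scen <- generate_scenario(scenario_config("regular", seed = 6,
                                            ages = 0:40, n_years = 40))
  expect_error(run_retrospective(scen$target, base = c(1950, 1979),
                                 horizon_end = 2030, models = "lee_carter"),
               class = "domain_error")
  expect_error(run_retrospective(scen$target, base = c(1950, 1979),
                                 horizon_end = 1979, models = "lee_carter"),
               class = "domain_error")
  # unknown model names surface as error rows, not aborts
  rep_ <- run_retrospective(scen$target, base = c(1950, 1979),
                            horizon_end = 1985, models = "nope")
  expect_identical(rep_$models$nope$status, "error:config_error")
})
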