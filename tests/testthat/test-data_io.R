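test_that("parse_hmd_table reads the 1x1 dialect", {
  s <- parse_hmd_table(hmd_toy_text(), sex = "female")
  expect_identical(s$ages, 0:1)
  expect_identical(s$years, 2000:2001)
  expect_equal(s$rates["0", "2000"], 0.005)
  expect_equal(as.vector(s$rates), c(0.005, 0.001, 0.0049, 0.0009))
  m <- parse_hmd_table(hmd_toy_text(), sex = "male")
  expect_equal(m$rates["1", "2001"], 0.0011)
})

test_that("age token 110+ sets the open-interval flag at age 110", {
  txt <- c("t", "", "Year Age Female Male Total",
           "2000 109 0.30 0.35 0.32", "2000 110+ 0.50 0.55 0.52",
           "2001 109 0.29 0.34 0.31", "2001 110+ 0.49 0.54 0.51")
  s <- parse_hmd_table(txt, sex = "female")
  expect_identical(max(s$ages), 110L)
  expect_true(s$open_interval)
})

test_that("parse errors are typed and informative", {
  # missing value "." inside the range
  txt <- hmd_toy_text()
  txt[7] <- "  2001           1          .   0.001 0.001"
  err <- expect_error(parse_hmd_table(txt, "female"), class = "missing_data_error")
  expect_match(conditionMessage(err), "2001")
  expect_match(conditionMessage(err), "1")
  # but the missing female value is ignored when parsing males
  expect_silent(parse_hmd_table(txt, "male"))
  # malformed row width, with line number
  bad <- hmd_toy_text(); bad[5] <- "  2000   1   0.001"
  err <- expect_error(parse_hmd_table(bad, "female"), class = "parse_error")
  expect_match(conditionMessage(err), "line 5")
  # non-contiguous years
  gap <- hmd_toy_text()[-c(6, 7)]
  gap <- c(gap, "  2003 0 0.004 0.005 0.0045", "  2003 1 0.0008 0.001 0.0009")
  expect_error(parse_hmd_table(gap, "female"), class = "contiguity_error")
  # absent (year, age) row
  holes <- hmd_toy_text()[-6]
  expect_error(parse_hmd_table(holes, "female"), class = "missing_data_error")
})

test_that("subset_surface extracts exact inclusive windows", {
  set.seed(3)
  m <- matrix(exp(rnorm(111 * 60, -4)), 111, 60)
  s <- mortality_surface(m, 0:110, 1950:2009)
  base <- subset_surface(s, year_range = c(1965, 1990))
  expect_identical(length(base$years), 26L)   # 1965..1990 inclusive
  expect_identical(base$years, 1965:1990)
  expect_equal(base$rates, s$rates[, as.character(1965:1990)])
  # identity
  full <- subset_surface(s, year_range = c(1950, 2009))
  expect_equal(full$rates, s$rates)
  # out of range
  err <- expect_error(subset_surface(s, year_range = c(1940, 1990)),
                      class = "out_of_range_error")
  expect_match(conditionMessage(err), "1950")
  expect_error(subset_surface(s, age_range = c(0, 120)),
               class = "out_of_range_error")
  # age subsetting drops the open-interval flag
  young <- subset_surface(s, age_range = c(0, 50))
  expect_false(young$open_interval)
})

test_that("long CSV round-trips a surface to 1e-15", {
  s <- toy_surface()
  path <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(s, path)
  s2 <- read_surface_csv(path)
  expect_equal(s2$rates, s$rates, tolerance = 1e-15)
  expect_identical(s2$population, s$population)
  expect_identical(s2$sex, s$sex)
  # with counts
  E <- matrix(1e5, nrow(s$rates), ncol(s$rates))
  sc <- mortality_surface(deaths = s$rates * E, exposures = E,
                          ages = s$ages, years = s$years, sex = s$sex)
  write_surface_csv(sc, path)
  sc2 <- read_surface_csv(path)
  expect_equal(sc2$deaths, sc$deaths, tolerance = 1e-15)
})

test_that("parse o format regenerates HMD numeric content exactly", {
  f <- toy_surface(seed = 1)
  m <- toy_surface(seed = 2); m$sex <- "male"
  txt <- format_hmd_table(f, m)
  expect_identical(parse_hmd_table(txt, "female")$rates, f$rates)
  expect_identical(parse_hmd_table(txt, "male")$rates, m$rates)
})

test_that("surface invariants are enforced", {
  expect_error(mortality_surface(matrix(c(1, -1), 2, 1), 0:1, 2000),
               class = "domain_error")
  expect_error(mortality_surface(matrix(1, 2, 2), c(0, 2), 2000:2001),
               class = "contiguity_error")
  # rates must agree with deaths/exposures
  expect_error(
    mortality_surface(matrix(0.5, 1, 1), 0, 2000,
                      deaths = matrix(2, 1, 1), exposures = matrix(10, 1, 1)),
    class = "domain_error")
})
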