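# Period life tables. e0, life expectancy at birth, is the headline metric
# every forecast is scored on, so the construction here is deliberately
# simple and fully deterministic: q(x) = m/(1 + (1-a) m) for closed
# intervals, open interval closed with q = 1, L = l/m, e = 1/m.

#' Build a period life table from a schedule of central death rates
#'
#' @param m numeric vector of central death rates per person-year, all > 0,
#'   one per single-year age starting at age `ages[1]`.
#' @param ages integer ages (default `0:(length(m)-1)`).
#' @param a0 average fraction of the year lived by those dying in the first
#'   age interval (default 0.1; infant deaths cluster early in the interval).
#' @param a_interior same for all other closed intervals (default 0.5).
#' @param open_interval logical; close the last age as an open interval
#'   (q = 1, L = l/m, e = 1/m). The package always forecasts on grids whose
#'   last age is open (110+).
#' @return a `data.frame` of class `life_table` with columns
#'   `x, m, a, q, l, d, L, T, e` (radix 1.0).
#' @examples
#' lt <- life_table(rep(0.01, 111), a0 = 0.5)
#' lt$e[1]  # exactly 100 under a constant hazard of 1/100
#' @export
life_table <- function(m, ages = seq_along(m) - 1L, a0 = 0.1,
                       a_interior = 0.5, open_interval = TRUE) {
  if (anyNA(m) || any(!is.finite(m)))
    abort_rmicast("domain_error", "death rates contain NA or non-finite values")
  if (any(m <= 0))
    abort_rmicast("domain_error", "all death rates must be > 0")
  if (a0 <= 0 || a0 >= 1 || a_interior <= 0 || a_interior >= 1)
    abort_rmicast("domain_error", "a0 and a_interior must lie in (0, 1)")
  n <- length(m)
  a <- c(a0, rep(a_interior, n - 1L))
  q <- m / (1 + (1 - a) * m)
  if (open_interval) q[n] <- 1
  q <- pmin(q, 1)
  l <- cumprod(c(1, 1 - q[-n]))
  d <- l * q
  L <- c(l[-1], 0) + a * d
  if (open_interval) L[n] <- l[n] / m[n]
  T <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T / l, 0)
  structure(data.frame(x = ages, m = m, a = a, q = q, l = l, d = d,
                       L = L, T = T, e = e),
            class = c("life_table", "data.frame"))
}

#' Life expectancy at birth from a rate schedule
#'
#' @inheritParams life_table
#' @return `e0` in years (a scalar).
#' @export
e0 <- function(m, a0 = 0.1, a_interior = 0.5, open_interval = TRUE) {
  life_table(m, a0 = a0, a_interior = a_interior,
             open_interval = open_interval)$e[1]
}

# Vectorized e0 over the columns of a rate matrix (ages x k). Used in the
# simulation loops where thousands of life tables are needed; identical math
# to life_table(), radix 1 so e0 = sum of L.
e0_matrix <- function(M, a0 = 0.1, a_interior = 0.5) {
  if (any(!is.finite(M)) || any(M <= 0))
    abort_rmicast("domain_error", "rate matrix must be finite and > 0")
  n <- nrow(M)
  a <- c(a0, rep(a_interior, n - 1L))
  Q <- M / (1 + (1 - a) * M)
  Q[n, ] <- 1
  e0s <- numeric(ncol(M))
  l <- rep(1, ncol(M))
  for (x in seq_len(n - 1L)) {
    dx <- l * Q[x, ]
    lnext <- l - dx
    e0s <- e0s + lnext + a[x] * dx
    l <- lnext
  }
  e0s + l / M[n, ]   # open-interval closure
}

#' Per-year life expectancy series of a mortality surface
#'
#' Applies [life_table()] to every year column of a surface.
#'
#' @param s a [mortality_surface()].
#' @inheritParams life_table
#' @return named numeric vector of e0, one entry per year.
#' @export
e0_series <- function(s, a0 = 0.1, a_interior = 0.5) {
  validate_surface(s)
  out <- tryCatch(
    e0_matrix(s$rates, a0 = a0, a_interior = a_interior),
    rmicast_error = function(e)
      abort_rmicast(class(e)[1], paste0("e0_series (", s$population, "): ",
                                        conditionMessage(e))))
  names(out) <- s$years
  out
}
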