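# Rates of mortality improvement rho(x,t) on the Lexis surface: the annual
# percent decline of the death rate at age x between years t-1 and t,
# rho(x,t) = 100 * (1 - m(x,t)/m(x,t-1)). Positive rho = improving survival.

#' Compute rates of mortality improvement
#'
#' @param s a [mortality_surface()] with at least two years.
#' @param classify logical; also attach band labels via [classify_bands()].
#' @return an object of class `improvement_surface`: list with `ages`,
#'   `years` (the first data year is dropped), `rho` (percent per year) and
#'   optionally `band`.
#' @export
improvement_rates <- function(s, classify = FALSE) {
  validate_surface(s)
  ny <- length(s$years)
  if (ny < 2)
    abort_rmicast("insufficient_data_error",
                  "improvement rates need at least 2 years of data")
  rho <- 100 * (1 - s$rates[, -1, drop = FALSE] / s$rates[, -ny, drop = FALSE])
  dimnames(rho) <- list(s$ages, s$years[-1])
  out <- structure(
    list(ages = s$ages, years = s$years[-1], rho = rho, band = NULL,
         population = s$population, sex = s$sex),
    class = "improvement_surface")
  if (classify) {
    out$band <- matrix(classify_bands(rho), nrow = nrow(rho),
                       dimnames = dimnames(rho))
  }
  out
}

#' Classify improvement rates into Lexis-map bands
#'
#' The four bands follow the conventional Lexis colour scheme: strong
#' improvements above 4 % per year, moderate between 0.5 and 4 %, stagnating
#' between -0.5 and +0.5 %, deteriorating below -0.5 %. Ties at -0.5 and
#' +0.5 fall to stagnating; the tie at 4 falls to moderate (improvements must
#' be strictly "more than 4 %" to count as strong).
#'
#' @param rho numeric vector/matrix of improvement rates in percent.
#' @return character vector of labels in
#'   `{"strong","moderate","stagnating","deteriorating"}`.
#' @examples
#' classify_bands(c(5, 2, 0, -3))
#' @export
classify_bands <- function(rho) {
  if (any(is.nan(rho)) || anyNA(rho))
    abort_rmicast("domain_error", "improvement rates contain NaN/NA")
  out <- character(length(rho))
  out[rho > 4] <- "strong"
  out[rho > 0.5 & rho <= 4] <- "moderate"
  out[rho >= -0.5 & rho <= 0.5] <- "stagnating"
  out[rho < -0.5] <- "deteriorating"
  out
}

# ---- two-dimensional P-spline smoothing ------------------------------------

# Cubic B-spline basis on an equally spaced knot grid (one knot every
# `spacing` units, extended `degree` knots beyond each end).
bspline_basis <- function(x, spacing = 5, degree = 3) {
  x0 <- min(x); x1 <- max(x)
  upper <- x0 + ceiling((x1 - x0) / spacing) * spacing   # >= x1
  knots <- seq(x0 - degree * spacing, upper + degree * spacing, by = spacing)
  splines::splineDesign(knots, x, ord = degree + 1)
}

# Order-d difference penalty matrix D'D for k coefficients.
diff_penalty <- function(k, d = 2) {
  D <- diff(diag(k), differences = d)
  crossprod(D)
}

# GLAM crossproduct: X'WX for X = kron(Bt, Bx) without forming X.
# Returns the (kx*kt) square matrix in vec(Theta[kx,kt]) column-major order.
glam_xtwx <- function(Bx, Bt, W) {
  kx <- ncol(Bx); kt <- ncol(Bt)
  Gx <- Bx[, rep(seq_len(kx), times = kx)] * Bx[, rep(seq_len(kx), each = kx)]
  Gt <- Bt[, rep(seq_len(kt), times = kt)] * Bt[, rep(seq_len(kt), each = kt)]
  M <- crossprod(Gx, W %*% Gt)            # (kx^2) x (kt^2)
  i <- rep(seq_len(kx), times = kt); j <- rep(seq_len(kt), each = kx)
  # row index pairs (i, i'), col pairs (j, j') -> M[(i'-1)kx+i, (j'-1)kt+j]
  ii <- outer(i, i, function(p, q) (q - 1L) * kx + p)
  jj <- outer(j, j, function(p, q) (q - 1L) * kt + p)
  K <- kx * kt
  out <- matrix(M[cbind(as.vector(ii), as.vector(jj))], K, K)
  out
}

psp2d <- function(Y, lambda_age, lambda_year, spacing, penalty_order,
                  weights = NULL, poisson = FALSE, exposures = NULL,
                  ages, years, max_iter = 30, tol = 1e-9,
                  last_year_cov = FALSE) {
  Bx <- bspline_basis(ages, spacing)
  Bt <- bspline_basis(years, spacing)
  kx <- ncol(Bx); kt <- ncol(Bt)
  P <- lambda_age * kronecker(diag(kt), diff_penalty(kx, penalty_order)) +
       lambda_year * kronecker(diff_penalty(kt, penalty_order), diag(kx))
  if (poisson) {
    # Poisson likelihood for deaths with log-exposure offset, IRLS
    off <- log(exposures)
    eta <- log((Y + 0.5) / exposures)     # working start at crude log rates
    XtWX <- NULL
    dev_old <- Inf
    for (it in seq_len(max_iter)) {
      mu <- exp(eta + off)
      W <- mu
      Z <- eta + (Y - mu) / mu
      XtWX <- glam_xtwx(Bx, Bt, W)
      A <- XtWX + P
      b <- as.vector(crossprod(Bx, (W * Z) %*% Bt))
      theta <- solve(A, b)
      eta <- Bx %*% matrix(theta, kx, kt) %*% t(Bt)
      mu <- exp(eta + off)
      dev <- 2 * sum(ifelse(Y > 0, Y * log(Y / mu), 0) - (Y - mu))
      if (abs(dev_old - dev) < tol * (abs(dev) + 0.1)) break
      dev_old <- dev
    }
  } else {
    W <- if (is.null(weights)) matrix(1, nrow(Y), ncol(Y)) else weights
    XtWX <- glam_xtwx(Bx, Bt, W)
    A <- XtWX + P
    b <- as.vector(crossprod(Bx, (W * Y) %*% Bt))
    theta <- solve(A, b)
    eta <- Bx %*% matrix(theta, kx, kt) %*% t(Bt)
    sigma2 <- sum(W * (Y - eta)^2) / max(length(Y) - 1, 1)
    XtWX <- XtWX / sigma2               # Gaussian information
    A <- A / sigma2                     # not exact for the penalty, see below
  }
  if (!last_year_cov) return(eta)
  # sandwich covariance of the fitted log rates in the last year:
  # V_theta = A^-1 (X'WX) A^-1 with A = X'WX + P (information + penalty)
  S <- solve(A)
  Vt <- S %*% XtWX %*% S
  R <- kronecker(matrix(Bt[nrow(Bt), ], 1), Bx)
  list(eta = eta, last_cov = R %*% Vt %*% t(R))
}

#' Smooth a mortality surface with two-dimensional penalized B-splines
#'
#' Fits a tensor-product cubic B-spline surface to the log death rates with
#' knots every `knot_spacing` ages/years and order-`penalty_order` difference
#' penalties in both directions. When death counts and exposures are present
#' the fit maximizes a penalized Poisson likelihood with log-exposure offset;
#' otherwise it falls back to penalized least squares on the log raw rates.
#' The penalty null space contains all bilinear log surfaces, so exponential
#' rate surfaces of the form `exp(linear in age and year)` pass through
#' unshrunk.
#'
#' @param s a [mortality_surface()]. Counts are used when both `deaths` and
#'   `exposures` are present.
#' @param lambda_age,lambda_year nonnegative penalty weights (default 10).
#' @param knot_spacing knot distance in years of age/time (default 5).
#' @param penalty_order difference-penalty order (default 2).
#' @param last_year_cov logical; attach the estimated covariance matrix of
#'   the fitted log rates in the last year (ages x ages) as attribute
#'   `"last_year_logcov"`. Used to propagate jump-off uncertainty into
#'   forecasts.
#' @return a `mortality_surface` with smoothed positive rates on the same
#'   grid (counts are dropped from the result: its rates are fitted, not
#'   observed).
#' @export
smooth_surface <- function(s, lambda_age = 10, lambda_year = 10,
                           knot_spacing = 5, penalty_order = 2,
                           last_year_cov = FALSE) {
  if (!is.finite(lambda_age) || !is.finite(lambda_year) ||
      lambda_age < 0 || lambda_year < 0)
    abort_rmicast("domain_error", "penalties must be finite and >= 0")
  use_counts <- !is.null(s$deaths) && !is.null(s$exposures)
  if (use_counts && (any(rowSums(s$deaths) == 0) ||
                     any(colSums(s$deaths) == 0)))
    abort_rmicast("degenerate_data_error",
                  "a row or column of the death counts is all zero")
  validate_surface(s)
  if (use_counts) {
    fitres <- psp2d(s$deaths, lambda_age, lambda_year, knot_spacing,
                    penalty_order, poisson = TRUE, exposures = s$exposures,
                    ages = s$ages, years = s$years,
                    last_year_cov = last_year_cov)
  } else {
    fitres <- psp2d(log(s$rates), lambda_age, lambda_year, knot_spacing,
                    penalty_order, ages = s$ages, years = s$years,
                    last_year_cov = last_year_cov)
  }
  eta <- if (last_year_cov) fitres$eta else fitres
  out <- mortality_surface(exp(eta), ages = s$ages, years = s$years,
                           population = s$population, sex = s$sex,
                           open_interval = s$open_interval)
  if (last_year_cov) attr(out, "last_year_logcov") <- fitres$last_cov
  out
}
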