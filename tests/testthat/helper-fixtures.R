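# Shared fixtures, all built in code.

# exact rank-1 Lee-Carter surface: log m = a + b k with sum(b)=1, sum(k)=0
lc_surface <- function(n_ages = 20, n_years = 15, drift = -1,
                       start_year = 1980, population = "LC", seed = 1) {
  set.seed(seed)
  ages <- seq_len(n_ages) - 1L
  years <- start_year + seq_len(n_years) - 1L
  a <- seq(-6, -1, length.out = n_ages)
  b_raw <- 0.5 + stats::runif(n_ages)
  b <- b_raw / sum(b_raw)
  k <- drift * (seq_len(n_years) - 1)
  k <- k - mean(k)
  m <- exp(a + outer(b, k))
  list(surface = mortality_surface(m, ages, years, population = population),
       a = a, b = b, k = k)
}

# small HMD-dialect text chunk: 2 years x 2 ages
hmd_toy_text <- function() {
  c("Toy, Death rates (period 1x1)", "",
    "  Year          Age         Female       Male       Total",
    "  2000           0          0.005000   0.006000   0.005500",
    "  2000           1          0.001000   0.001200   0.001100",
    "  2001           0          0.004900   0.005900   0.005400",
    "  2001           1          0.000900   0.001100   0.001000")
}

# surface with a smooth non-trivial shape for io round trips
toy_surface <- function(n_ages = 6, n_years = 5, seed = 7) {
  set.seed(seed)
  ages <- 0:(n_ages - 1); years <- 2000 + 0:(n_years - 1)
  m <- exp(outer(seq(-7, -2, length.out = n_ages),
                 seq(0, -0.3, length.out = n_years), `+`) +
             matrix(stats::rnorm(n_ages * n_years, 0, 0.05), n_ages))
  mortality_surface(m, ages, years, population = "TOY", sex = "female")
}

# fine-grid survival oracle for a continuous hazard mu(x): returns e0 and
# the interval central death rates m_x = (integral S mu)/(integral S),
# computed by trapezoid on a step grid; independent of life_table()
hazard_oracle <- function(mu_fun, max_age = 110, step = 0.01) {
  x <- seq(0, max_age + 1, by = step)
  mu <- mu_fun(x)
  H <- c(0, cumsum((mu[-1] + mu[-length(mu)]) / 2 * step))
  S <- exp(-H)
  # e0 = integral of S over closed ages + open-interval tail S(A)/mu(A)
  A_idx <- which(x >= max_age)[1]
  e0_closed <- sum((S[-1] + S[-length(S)]) / 2 * step * (x[-1] <= max_age))
  e0_oracle <- e0_closed + S[A_idx] / mu[A_idx]
  m_x <- vapply(0:(max_age - 1), function(a) {
    i <- x >= a & x <= a + 1
    deaths <- sum((S * mu)[i][-1] * step)
    expo <- sum(S[i][-1] * step)
    deaths / expo
  }, numeric(1))
  list(e0 = e0_oracle, m = c(m_x, mu[A_idx]))
}
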