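# Shared in-code fixtures for the test suite.

# DI points on an exact logistic curve 1 + 5 / (1 + exp(-(doy - t0)/s)).
# The analytic DI = 5.5 crossing is at t0 + s * log(9).
logistic_di_points <- function(doys, t0, s, site = "S", year = 2000,
                               n = 50) {
  tibble::tibble(
    site = site, year = year, doy = doys,
    di = 1 + 5 / (1 + exp(-(doys - t0) / s)),
    n_individuals = n
  )
}

# Constant-weather table: `days` identical days for one site.
constant_weather <- function(days, tmin, tmax, site = "W1",
                             start = as.Date("2001-01-01")) {
  tibble::tibble(
    site = site,
    date = start + seq_len(days) - 1,
    tmin_c = tmin,
    tmax_c = tmax
  )
}

# Numeric-integration oracle for single-sine degree days: mean of the
# clipped sine over one 24 h cycle by adaptive quadrature, with the domain
# split at the threshold-crossing times (adaptive rules lose accuracy at
# the clip kinks otherwise).
sine_dd_oracle <- function(tmin, tmax, ldt) {
  tm <- (tmin + tmax) / 2
  a <- (tmax - tmin) / 2
  f <- function(t) pmax(tm + a * sin(2 * pi * t / 24) - ldt, 0)
  cuts <- c(0, 24)
  if (a > 0 && ldt > tmin && ldt < tmax) {
    s <- asin((ldt - tm) / a)
    phi <- c(s, pi - s) %% (2 * pi)
    cuts <- sort(unique(c(0, 24 * phi / (2 * pi), 24)))
  }
  pieces <- vapply(seq_len(length(cuts) - 1), function(j) {
    stats::integrate(f, cuts[j], cuts[j + 1], rel.tol = 1e-10,
                     abs.tol = 1e-12, subdivisions = 500L)$value
  }, numeric(1))
  sum(pieces) / 24
}

# Noiseless rearing observations on the model surfaces for one group.
model_surface_obs <- function(c_dev, q10_dev, c_growth, q10_growth,
                              tvars = c(2, 4), n_per_tvar = 10) {
  tvar <- rep(tvars, each = n_per_tvar)
  d <- development_days(c_dev, q10_dev, tvar)
  tibble::tibble(
    site = "X", photoperiod = "long", sex = "female",
    tvar_c = tvar, dev_days = d,
    mass_g = adult_mass(c_growth, d, q10_growth, tvar)
  )
}
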