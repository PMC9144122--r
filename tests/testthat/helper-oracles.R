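# Independent reference curves used across tests.

# Arrival-time CDF by brute-force grid convolution of
# Uniform(0, fwhm) (x) Exp(turnoff) (x) Exp(tau0) -- a numeric route
# independent of the package's closed-form expressions.
oracle_arrival_cdf <- function(pulse, fluor, tmax = 60, dt = 0.002) {
  tg <- seq(0, tmax, by = dt)
  d1 <- stats::dexp(tg, 1 / pulse$turnoff_ns)
  d2 <- stats::dexp(tg, 1 / fluor$tau0_ns)
  f <- if (pulse$fwhm_ns > 0) {
    du <- stats::dunif(tg, 0, pulse$fwhm_ns)
    stats::convolve(du, rev(d1), type = "open")[seq_along(tg)] * dt
  } else {
    d1
  }
  f <- stats::convolve(f, rev(d2), type = "open")[seq_along(tg)] * dt
  cdf <- pmin(cumsum(c(0, (f[-1] + f[-length(f)]) / 2)) * dt, 1)
  stats::approxfun(tg, cdf, yleft = 0, yright = 1)
}

# CDF of detected (first-photon) times from the closed-form detected-event
# intensity, normalised by its total mass.
detected_cdf_fun <- function(rate, n_pixel, pulse, fluor, tmax = 200) {
  tg <- seq(0, tmax, length.out = 8001)
  dens <- detected_density(tg, rate, n_pixel, pulse, fluor)
  cdf <- cumsum(c(0, diff(tg) * (dens[-1] + dens[-length(dens)]) / 2))
  cdf <- cdf / (n_pixel * (1 - exp(-rate / n_pixel)))
  stats::approxfun(tg, pmin(cdf, 1), yleft = 0, yright = 1)
}

# Exact expected histogram of arrival times (no pile-up, no noise) scaled
# to n_counts photons.
expected_histogram <- function(n_counts, pulse, fluor, config) {
  edges <- seq(0, config$tw_ns, by = config$tres_ns)
  pr <- pmax(0, arrival_cdf(edges[-1], pulse, fluor) -
                  arrival_cdf(edges[-length(edges)], pulse, fluor))
  tcspc_histogram(n_counts * pr, config$tres_ns, config$tw_ns)
}

# Pure single-exponential histogram evaluated at bin centers.
exp_histogram <- function(i0, tau, tres = 0.3125, tw = 35) {
  tc <- seq(tres / 2, tw - tres / 2, by = tres)
  tcspc_histogram(i0 * exp(-tc / tau), tres, tw)
}

ks_distance <- function(x, cdf_fun) {
  unname(suppressWarnings(stats::ks.test(x, cdf_fun))$statistic)
}
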