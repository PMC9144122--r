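# synthetic delta-tau curve: falling statistics branch + rising pile-up
# branch that crosses 0.055 at exactly rate = 0.31 (log-linear, so the
# interpolation in find_max_count_rate is exact)
synthetic_scan <- function(rates, delta) {
  structure(list(table = data.frame(rate = rates, delta_tau = delta,
                                    mean_tau = 5, n_ok = 100L, n_fail = 0L),
                 taus = list(), n_pixel = 1L, tau0_ns = 5, n_rep = 100L),
            class = "pileup_scan")
}

test_that("the threshold crossing is located exactly on a constructed curve", {
  rates <- 10^seq(log10(0.02), log10(1), length.out = 25)
  delta <- pmax(0.03 * sqrt(0.05 / rates), 0.055 * (rates / 0.31)^2)
  sc <- synthetic_scan(rates, delta)
  expect_equal(find_max_count_rate(sc, threshold = 0.055), 0.31,
               tolerance = 1e-10)
})

test_that("missing crossings raise instructive errors", {
  rates <- 10^seq(-2, 0, length.out = 10)
  expect_error(find_max_count_rate(synthetic_scan(rates, rep(0.01, 10)),
                                   threshold = 0.055),
               "higher rates")
  expect_error(find_max_count_rate(synthetic_scan(rates, rep(0.2, 10)),
                                   threshold = 0.055),
               "never reaches")
})

test_that("through-origin slope fitting is exact and robust", {
  pts <- data.frame(n_pixel = c(1, 3, 10, 30, 100),
                    max_rate = 0.31 * c(1, 3, 10, 30, 100))
  expect_equal(fit_pixel_slope(pts)$slope, 0.31, tolerance = 1e-12)
  expect_equal(fit_pixel_slope(data.frame(n_pixel = 10,
                                          max_rate = 3.1))$slope, 0.31)
  expect_error(fit_pixel_slope(data.frame(n_pixel = numeric(0),
                                          max_rate = numeric(0))),
               "at least one")

  # multiplicative +-10% noise can perturb the fitted slope by at most 10%
  set.seed(401)
  for (i in 1:1000) {
    noisy <- pts
    noisy$max_rate <- noisy$max_rate * runif(5, 0.9, 1.1)
    expect_lt(abs(fit_pixel_slope(noisy)$slope / 0.31 - 1), 0.1)
  }
})

test_that("rebinning sums adjacent bins and conserves counts", {
  h <- exp_histogram(500, 5)  # 112 bins
  expect_identical(rebin_histogram(h, 1), h)
  for (f in c(2, 3, 5, 7, 112, 200)) {
    r <- rebin_histogram(h, f)
    expect_equal(sum(r$counts), sum(h$counts))
    expect_equal(r$tres_ns, h$tres_ns * f)
  }
  expect_equal(length(rebin_histogram(h, 112)$counts), 1L)
  expect_equal(rebin_histogram(h, 2)$counts[1], h$counts[1] + h$counts[2])
  expect_error(rebin_histogram(h, 0), "must be")
})

test_that("rebinned noiseless decays refit exactly", {
  h <- exp_histogram(1000, 5)
  # factors dividing the bin count: group sums stay proportional to the
  # exponential at the new bin centers, so the fit is exact
  for (f in c(2, 4, 8, 14)) {
    tau <- fit_lifetime(rebin_histogram(h, f))$tau_fit_ns
    expect_lt(abs(tau / 5 - 1), 1e-8)
  }
})

test_that("pile-up scans are reproducible with a fixed seed", {
  cfg <- detector_config(nw = 500)
  s1 <- scan_count_rate(c(0.5, 1, 2), 2, laser_pulse(), fluorophore(5),
                        noise_model(0.01), cfg, n_rep = 3, seed = 42)
  s2 <- scan_count_rate(c(0.5, 1, 2), 2, laser_pulse(), fluorophore(5),
                        noise_model(0.01), cfg, n_rep = 3, seed = 42)
  expect_identical(s1$table, s2$table)
  expect_error(scan_count_rate(c(2, 1), 1, laser_pulse(), fluorophore(5),
                               noise_model(0), cfg, n_rep = 3),
               "increasing")
})

test_that("accuracy versus rate is U-shaped for a single pixel", {
  set.seed(402)
  rates <- c(0.02, 0.05, 0.12, 0.3, 0.7, 1.5, 3)
  sc <- scan_count_rate(rates, 1, laser_pulse(), fluorophore(5),
                        noise_model(0.01), detector_config(nw = 3000),
                        n_rep = 50, seed = 402)
  d <- sc$table$delta_tau
  n <- length(d)
  sm <- stats::filter(log(d), rep(1 / 3, 3))
  sm[1] <- log(d[1]); sm[n] <- log(d[n])
  i_min <- which.min(sm)
  expect_gt(i_min, 1)        # a decreasing, statistics-dominated prefix
  expect_lt(i_min, n)        # an increasing, pile-up-dominated suffix
  expect_gt(d[1], min(d))
  expect_gt(d[n], 2 * min(d))
})

test_that("the resolution scan reports accuracy per binning factor", {
  rs <- scan_resolution(c(0.5, 2, 6), rate = 1000 / 30000,
                        config = detector_config(nw = 30000),
                        n_rep = 15, seed = 403)
  expect_identical(nrow(rs$table), 3L)
  expect_true(all(is.finite(rs$table$delta_tau)))
  expect_equal(rs$table$tres_ns,
               rs$table$rebin_factor * 0.3125)
  expect_error(scan_resolution(c(2, 1), rate = 0.03), "increasing")
  expect_error(scan_resolution(c(500), rate = 0.03), "exceeds")
})
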