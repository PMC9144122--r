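test_that("fit recovers the lifetime exactly from a noiseless decay", {
  h <- exp_histogram(1000, 5)
  fit <- fit_lifetime(h)
  expect_equal(fit$tau_fit_ns, 5, tolerance = 1e-6)
  expect_equal(fit$i0, 1000, tolerance = 1e-4)
  expect_identical(fit$fit_start_bin, 2L)  # one bin after the maximum

  # too few populated bins inside the fit range
  sparse <- tcspc_histogram(c(10, 3, 0, 0), tres_ns = 1, tw_ns = 4)
  expect_error(fit_lifetime(sparse), "two bins")
})

test_that("the fit start can skip the excitation transient", {
  # exact expected histogram including the pulse convolution: fitting right
  # after the peak is biased high by the turn-off tail, skipping five
  # turn-off constants removes the bias
  pulse <- laser_pulse()
  fluor <- fluorophore(5)
  h <- expected_histogram(1e6, pulse, fluor, detector_config())
  biased <- fit_lifetime(h)$tau_fit_ns
  clean <- fit_lifetime(h, skip_ns = pipeline_skip_ns(pulse))$tau_fit_ns
  expect_gt(biased / 5 - 1, 0.01)
  expect_lt(abs(clean / 5 - 1), 0.002)
})

test_that("precision and accuracy statistics match hand computations", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(4, 6)), sqrt(2) / 5)
  expect_error(coefficient_of_variation(5), "two values")

  expect_equal(relative_error(c(5, 5), 5), 0)
  expect_equal(relative_error(c(4.5, 5.5), 5), 0.1)
  expect_error(relative_error(c(5), -1), "must be")

  expect_equal(aggregate_geometric(10)$gmean, 10)
  expect_equal(aggregate_geometric(c(1, 100))$gmean, 10)
  expect_equal(aggregate_geometric(c(2, 4, 8))$gmean, 4)
  expect_error(aggregate_geometric(c(1, -2)), "positive")
})

test_that("delta-tau of unbiased Gaussian estimates is the folded-normal mean", {
  set.seed(301)
  cv <- 0.05
  taus <- rnorm(1e4, mean = 5, sd = 5 * cv)
  expect_lt(abs(relative_error(taus, 5) / (sqrt(2 / pi) * cv) - 1), 0.05)
})

test_that("pipeline fits are unbiased at low rate and biased low under pile-up", {
  pulse <- laser_pulse()
  fluor <- fluorophore(5)
  set.seed(302)
  cfg <- detector_config(n_pixel = 100)
  taus <- replicate(50, {
    m <- simulate_measurement(pulse, fluor, noise_model(0), 1000 / 30000, cfg)
    fit_lifetime(m$histogram, skip_ns = pipeline_skip_ns(pulse))$tau_fit_ns
  })
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - 5), 3 * se)

  # one pixel at high rate: strong first-photon bias
  m_hi <- simulate_measurement(pulse, fluor, noise_model(0), 3,
                               detector_config(n_pixel = 1))
  tau_hi <- fit_lifetime(m_hi$histogram,
                         skip_ns = pipeline_skip_ns(pulse))$tau_fit_ns
  expect_lt(tau_hi, 4.5)
})

test_that("precision is independent of the absolute lifetime at matched counts", {
  pulse <- laser_pulse()
  set.seed(303)
  cv_of <- function(tau0) {
    fluor <- fluorophore(tau0)
    cfg <- detector_config(n_pixel = 100, pileup = FALSE)
    taus <- replicate(60, {
      m <- simulate_measurement(pulse, fluor, noise_model(0), 1000 / 30000,
                                cfg)
      fit_lifetime(m$histogram, skip_ns = pipeline_skip_ns(pulse))$tau_fit_ns
    })
    coefficient_of_variation(taus)
  }
  expect_lt(abs(log(cv_of(5) / cv_of(10))), 0.3)
})

test_that("mean fitted lifetime is non-increasing in the count rate", {
  pulse <- laser_pulse()
  fluor <- fluorophore(5)
  mean_tau <- sapply(c(0.1, 1, 3, 10), function(r) {
    set.seed(304)  # paired seeds across rates
    taus <- replicate(8, fit_lifetime(
      simulate_measurement(pulse, fluor, noise_model(0), r,
                           detector_config(n_pixel = 1, nw = 1e4))$histogram,
      skip_ns = pipeline_skip_ns(pulse))$tau_fit_ns)
    mean(taus)
  })
  expect_true(all(diff(mean_tau) < 0))
})
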