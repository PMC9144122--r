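test_that("pixel assignment is uniform over the array", {
  expect_identical(assign_pixels(numeric(0), 5), integer(0))
  expect_true(all(assign_pixels(1:7, 1) == 1L))
  expect_error(assign_pixels(1:3, 0), "must be")
  set.seed(201)
  lab <- assign_pixels(runif(1e5), 10)
  freq <- tabulate(lab, 10)
  expect_true(all(abs(freq - 1e4) < 3 * sqrt(1e4)))
})

test_that("pile-up keeps only the earliest photon per pixel and window", {
  ev <- data.frame(window = c(1L, 1L), pixel = c(1L, 1L),
                   time_ns = c(1.0, 2.0))
  expect_equal(apply_pileup(ev)$time_ns, 1.0)

  ev9 <- data.frame(window = 1L, pixel = 1:5, time_ns = c(3, 1, 4, 2, 5))
  expect_equal(nrow(apply_pileup(ev9)), 5L)  # distinct pixels: all kept

  expect_identical(apply_pileup(ev, pileup_enabled = FALSE), ev)

  # tie on one pixel: exactly one survives, the first-generated one
  tie <- data.frame(window = c(2L, 2L), pixel = c(3L, 3L),
                    time_ns = c(1.5, 1.5))
  kept <- apply_pileup(tie)
  expect_identical(rownames(kept), "1")

  # property: never more than one detected event per (window, pixel)
  set.seed(202)
  ev <- data.frame(window = sample.int(50, 2000, replace = TRUE),
                   pixel = sample.int(4, 2000, replace = TRUE),
                   time_ns = runif(2000, 0, 35))
  det <- apply_pileup(ev)
  expect_true(all(table(det$window, det$pixel) <= 1))
  expect_true(all(tapply(ev$time_ns, interaction(ev$window, ev$pixel), min,
                         simplify = TRUE)[
    paste(det$window, det$pixel, sep = ".")] == det$time_ns))
})

test_that("quantization uses half-open bins and conserves events", {
  cfg <- detector_config(tres_ns = 0.5, tw_ns = 10, nw = 1)
  h <- quantize_and_histogram(c(0, 0.5, 0.49999, 9.999, 10, 12), cfg)
  expect_equal(h$counts[1], 2)      # t = 0 and t just below tres
  expect_equal(h$counts[2], 1)      # t = tres exactly -> bin 2 (index 1)
  expect_equal(h$n_dropped, 2)      # t >= tw dropped
  expect_equal(sum(h$counts) + h$n_dropped, 6)
  expect_true(all(h$counts >= 0))
})

test_that("full measurement conserves counts and respects the pixel cap", {
  set.seed(203)
  cfg <- detector_config(n_pixel = 3, tw_ns = 1e5, nw = 500, pileup = FALSE)
  m <- simulate_measurement(laser_pulse(), fluorophore(5), noise_model(0.05),
                            rate = 2, config = cfg)
  # no pile-up, window long enough: everything detected
  expect_equal(m$n_detected, m$n_arrived + m$n_noise)
  expect_equal(sum(m$histogram$counts) + m$histogram$n_dropped, m$n_detected)

  cfg$pileup <- TRUE
  m2 <- simulate_measurement(laser_pulse(), fluorophore(5), noise_model(0.05),
                             rate = 2, config = cfg)
  expect_lte(m2$n_detected, m2$n_arrived + m2$n_noise)
  expect_lte(m2$n_detected, cfg$n_pixel * cfg$nw)

  empty <- simulate_measurement(laser_pulse(), fluorophore(5), noise_model(0),
                                rate = 0, config = detector_config(nw = 100))
  expect_equal(sum(empty$histogram$counts), 0)
})

test_that("bin-level and exact-time pile-up reductions give one histogram", {
  set.seed(204)
  cfg <- detector_config(n_pixel = 2, nw = 2000)
  set.seed(11)
  fast <- simulate_measurement(laser_pulse(), fluorophore(5),
                               noise_model(0.01), 3, cfg)
  set.seed(11)
  exact <- simulate_measurement(laser_pulse(), fluorophore(5),
                                noise_model(0.01), 3, cfg, keep_times = TRUE)
  expect_identical(fast$histogram$counts, exact$histogram$counts)
  expect_identical(fast$n_detected, exact$n_detected)
})

test_that("expected detections never decrease with more pixels", {
  det <- sapply(c(1, 2, 5, 10), function(np) {
    set.seed(205)
    simulate_measurement(laser_pulse(), fluorophore(5), noise_model(0),
                         rate = 2,
                         config = detector_config(n_pixel = np,
                                                  nw = 1e4))$n_detected
  })
  expect_true(all(diff(det) >= 0))
})

test_that("pile-up is negligible when the rate is far below the pixel count", {
  set.seed(206)
  cfg_on <- detector_config(n_pixel = 100, nw = 30000)
  cfg_off <- detector_config(n_pixel = 100, nw = 30000, pileup = FALSE)
  h1 <- simulate_measurement(laser_pulse(), fluorophore(5), noise_model(0),
                             0.033, cfg_on)$histogram
  h2 <- simulate_measurement(laser_pulse(), fluorophore(5), noise_model(0),
                             0.033, cfg_off)$histogram
  # pool into coarse bins with decent expected counts, then two-sample
  # chi-square on the pair of histograms
  grp <- pmin((seq_along(h1$counts) - 1) %/% 16, 7)
  tab <- cbind(tapply(h1$counts, grp, sum), tapply(h2$counts, grp, sum))
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("detected-event density has the correct mass and thin limit", {
  pulse <- laser_pulse()
  fluor <- fluorophore(5)
  for (mu in c(0.3, 3)) for (np in c(1L, 10L)) {
    mass <- stats::integrate(function(t) detected_density(t, mu, np, pulse,
                                                          fluor),
                             0, Inf, rel.tol = 1e-8)$value
    expect_equal(mass, np * (1 - exp(-mu / np)), tolerance = 1e-5)
  }
  # mu/N -> 0: density -> mu * f(t) pointwise
  tg <- seq(0.5, 30, by = 0.5)
  mu <- 1e-4
  expect_equal(detected_density(tg, mu, 1L, pulse, fluor),
               mu * arrival_density(tg, pulse, fluor), tolerance = 1e-3)
})

test_that("simulated detected times match the first-photon density", {
  pulse <- laser_pulse()
  fluor <- fluorophore(5)
  set.seed(207)
  m <- simulate_measurement(pulse, fluor, noise_model(0), rate = 3,
                            config = detector_config(n_pixel = 1, nw = 1e5),
                            keep_times = TRUE)
  expect_lt(ks_distance(m$times_detected,
                        detected_cdf_fun(3, 1, pulse, fluor)), 0.02)
})
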