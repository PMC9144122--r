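#' Replicate simulate-and-fit runs
#'
#' Runs `n_rep` independent measurements at one count rate and fits each
#' histogram.  Fit failures (e.g. too few populated bins) are excluded and
#' counted.
#'
#' @param rate Mean photons per window.
#' @param pulse,fluor,noise,config Simulation models.
#' @param n_rep Number of replicates (>= 1).
#' @return A list with `taus` (successful fits) and `n_fail`.
#' @keywords internal
replicate_fits <- function(rate, pulse, fluor, noise, config, n_rep) {
  skip <- pipeline_skip_ns(pulse)
  taus <- numeric(0)
  n_fail <- 0L
  for (i in seq_len(n_rep)) {
    m <- simulate_measurement(pulse, fluor, noise, rate, config)
    tau <- tryCatch(fit_lifetime(m$histogram, skip_ns = skip)$tau_fit_ns,
                    error = function(e) NA_real_)
    if (is.na(tau)) n_fail <- n_fail + 1L else taus <- c(taus, tau)
  }
  list(taus = taus, n_fail = n_fail)
}

#' Pile-up-free accuracy at a reference photon count
#'
#' Self-calibrates the accuracy threshold used to locate the maximum count
#' rate: the relative error delta-tau obtained without pile-up at
#' `n_counts` total photons (rate `n_counts / nw`), under the same pulse,
#' noise and fitting conditions as the scan itself.  This reproduces the
#' "accuracy corresponding to 1000 photon counts" operating point without
#' hard-coding an absolute percentage, which would embed a specific noise
#' floor.
#'
#' @param pulse,fluor,noise Simulation models.
#' @param config A [detector_config()]; its `pileup` flag is ignored
#'   (forced off) and its `n_pixel` is irrelevant without pile-up.
#' @param n_counts Reference photon counts; default 1000.
#' @param n_rep Replicates; default 100.
#' @param seed Optional RNG seed.
#' @return A list with `threshold` (delta-tau), `taus`, `n_fail`,
#'   `n_counts`.
#' @export
calibrate_accuracy_threshold <- function(pulse, fluor, noise, config,
                                         n_counts = 1000, n_rep = 100,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$pileup <- FALSE
  rate <- n_counts / cfg$nw
  r <- replicate_fits(rate, pulse, fluor, noise, cfg, n_rep)
  list(threshold = relative_error(r$taus, fluor$tau0_ns),
       taus = r$taus, n_fail = r$n_fail, n_counts = n_counts)
}

#' Accuracy versus count rate (pile-up scan)
#'
#' For each count rate in `rate_grid`, runs `n_rep` independent simulated
#' measurements with pile-up, fits every histogram, and records the
#' relative error delta-tau.  The number of measurement windows is held
#' fixed, so increasing the rate first improves the accuracy (more
#' photons) and then degrades it as pile-up biases the lifetime low.
#'
#' @param rate_grid Strictly increasing vector of mean photons per window.
#' @param n_pixel Number of pixels for this scan.
#' @param pulse,fluor,noise Simulation models.
#' @param config A [detector_config()]; `n_pixel` and `pileup = TRUE` are
#'   imposed.
#' @param n_rep Replicates per grid point (>= 3).
#' @param seed Optional RNG seed.
#' @return An object of class `pileup_scan`: a list with `table` (data
#'   frame `rate`, `delta_tau`, `mean_tau`, `n_ok`, `n_fail`), `taus`
#'   (list of replicate vectors), `n_pixel`, `tau0_ns`.
#' @export
scan_count_rate <- function(rate_grid, n_pixel, pulse, fluor,
                            noise = noise_model(), config = detector_config(),
                            n_rep = 100, seed = NULL) {
  if (length(rate_grid) < 1L || any(diff(rate_grid) <= 0))
    stop("`rate_grid` must be nonempty and strictly increasing",
         call. = FALSE)
  check_count(n_rep, "n_rep", lower = 3)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$n_pixel <- as.integer(n_pixel)
  cfg$pileup <- TRUE
  taus <- vector("list", length(rate_grid))
  tab <- data.frame(rate = rate_grid, delta_tau = NA_real_,
                    mean_tau = NA_real_, n_ok = 0L, n_fail = 0L)
  total_fail <- 0L
  for (i in seq_along(rate_grid)) {
    r <- replicate_fits(rate_grid[i], pulse, fluor, noise, cfg, n_rep)
    taus[[i]] <- r$taus
    tab$delta_tau[i] <- if (length(r$taus))
      relative_error(r$taus, fluor$tau0_ns) else NA_real_
    tab$mean_tau[i] <- if (length(r$taus)) mean(r$taus) else NA_real_
    tab$n_ok[i] <- length(r$taus)
    tab$n_fail[i] <- r$n_fail
    total_fail <- total_fail + r$n_fail
  }
  if (total_fail > 0L)
    warning(sprintf("%d of %d fits failed and were excluded", total_fail,
                    length(rate_grid) * n_rep), call. = FALSE)
  structure(list(table = tab, taus = taus, n_pixel = as.integer(n_pixel),
                 tau0_ns = fluor$tau0_ns, n_rep = n_rep),
            class = "pileup_scan")
}

#' @export
print.pileup_scan <- function(x, ...) {
  cat(sprintf("<pileup_scan> %d pixel(s), %d rates in [%.3g, %.3g], %d reps\n",
              x$n_pixel, nrow(x$table), min(x$table$rate), max(x$table$rate),
              x$n_rep))
  invisible(x)
}

#' Maximum count rate before pile-up exceeds an accuracy threshold
#'
#' Locates, on the rising (pile-up-dominated) branch of the delta-tau
#' curve, the rate at which the accuracy crosses `threshold`.  The rising
#' branch starts at the minimum of the (3-point moving-average smoothed)
#' curve; the crossing is interpolated log-linearly (linear in log rate /
#' log delta-tau) between the last grid point at or below the threshold
#' and the first above it.
#'
#' @param scan A [scan_count_rate()] result.
#' @param threshold Accuracy threshold delta-tau (> 0), typically from
#'   [calibrate_accuracy_threshold()].
#' @return The interpolated maximum count rate `<Nc>_w,max` in photons per
#'   window.
#' @export
find_max_count_rate <- function(scan, threshold) {
  stopifnot(inherits(scan, "pileup_scan"))
  check_scalar(threshold, "threshold", lower = 0, strict = TRUE)
  tab <- scan$table[!is.na(scan$table$delta_tau), ]
  d <- tab$delta_tau
  r <- tab$rate
  n <- length(d)
  if (n < 2L)
    stop("not enough valid grid points in the scan", call. = FALSE)
  ## smooth on the log scale to locate the minimum robustly
  ld <- log(d)
  sm <- ld
  if (n >= 3L)
    sm[2:(n - 1)] <- (ld[1:(n - 2)] + ld[2:(n - 1)] + ld[3:n]) / 3
  i_min <- which.min(sm)
  if (d[i_min] > threshold)
    stop("accuracy never reaches the threshold on this grid; ",
         "extend the rate grid towards lower rates or lower the threshold",
         call. = FALSE)
  rising <- i_min:n
  above <- rising[d[rising] > threshold]
  if (length(above) == 0L)
    stop("accuracy stays below the threshold on the rising branch; ",
         "extend the rate grid towards higher rates", call. = FALSE)
  j <- above[1]
  i <- max(which(d[i_min:(j - 1)] <= threshold)) + i_min - 1L
  ## log-linear interpolation
  lx <- log(r[c(i, j)])
  ly <- log(d[c(i, j)])
  exp(lx[1] + (lx[2] - lx[1]) * (log(threshold) - ly[1]) / (ly[2] - ly[1]))
}

#' Default log-spaced rate grid for a pile-up scan
#'
#' Log-spaced count rates spanning `span[1] * n_pixel` to
#' `span[2] * n_pixel` photons per window.  The span brackets the expected
#' per-pixel maximum rate (~0.3/pixel) with margin on both sides.
#'
#' @param n_pixel Number of pixels.
#' @param span Multiples of `n_pixel` for the grid ends; default
#'   `c(0.05, 1.2)`.
#' @param points_per_decade Grid density; default 8.
#' @return Numeric vector of rates.
#' @export
default_rate_grid <- function(n_pixel, span = c(0.05, 1.2),
                              points_per_decade = 8) {
  n_pts <- max(2L, ceiling(points_per_decade * log10(span[2] / span[1])) + 1L)
  10^seq(log10(span[1] * n_pixel), log10(span[2] * n_pixel),
         length.out = n_pts)
}

#' Maximum count rate versus pixel count
#'
#' The central pile-up experiment: for each pixel count, scan delta-tau
#' over a log-spaced rate grid (at fixed `nw`), self-calibrate the accuracy
#' threshold to the pile-up-free accuracy at `n_counts_ref` photons, and
#' extract the maximum tolerable count rate.  The resulting
#' (pixel count, max rate) points are fitted through the origin by
#' [fit_pixel_slope()]; the slope is the maximum count rate *per pixel*.
#'
#' @param n_pixels Vector of pixel counts, e.g. `c(1, 3, 10, 30, 100)`.
#' @param pulse,fluor,noise Simulation models.
#' @param config Base [detector_config()] (its `n_pixel` is overridden).
#' @param n_rep Replicates per grid point; default 30.
#' @param n_counts_ref Reference photon counts for the threshold;
#'   default 1000.
#' @param threshold Optional fixed delta-tau threshold overriding the
#'   self-calibration.
#' @param span,points_per_decade Passed to [default_rate_grid()].
#' @param seed Optional RNG seed; expanded into independent sub-seeds for
#'   the calibration and each pixel count.
#' @return An object of class `max_rate_scan`: list with `points` (data
#'   frame `n_pixel`, `max_rate`), `threshold`, `slope_fit`
#'   (a [fit_pixel_slope()] result) and the per-pixel `scans`.
#' @export
max_rate_vs_pixels <- function(n_pixels = c(1, 3, 10, 30, 100),
                               pulse = laser_pulse(), fluor = fluorophore(),
                               noise = noise_model(),
                               config = detector_config(),
                               n_rep = 30, n_counts_ref = 1000,
                               threshold = NULL,
                               span = c(0.05, 1.2), points_per_decade = 8,
                               seed = NULL) {
  seeds <- derive_seeds(seed, length(n_pixels) + 1L)
  if (is.null(threshold)) {
    cal <- calibrate_accuracy_threshold(pulse, fluor, noise, config,
                                        n_counts = n_counts_ref,
                                        n_rep = max(n_rep, 100),
                                        seed = seeds[[1]])
    threshold <- cal$threshold
  } else {
    cal <- NULL
  }
  scans <- vector("list", length(n_pixels))
  max_rate <- numeric(length(n_pixels))
  for (k in seq_along(n_pixels)) {
    grid <- default_rate_grid(n_pixels[k], span, points_per_decade)
    scans[[k]] <- scan_count_rate(grid, n_pixels[k], pulse, fluor, noise,
                                  config, n_rep = n_rep,
                                  seed = seeds[[k + 1L]])
    max_rate[k] <- find_max_count_rate(scans[[k]], threshold)
  }
  points <- data.frame(n_pixel = n_pixels, max_rate = max_rate)
  structure(list(points = points, threshold = threshold,
                 calibration = cal, scans = scans,
                 slope_fit = fit_pixel_slope(points)),
            class = "max_rate_scan")
}

#' @export
print.max_rate_scan <- function(x, ...) {
  cat(sprintf("<max_rate_scan> threshold delta_tau = %.3g\n", x$threshold))
  print(x$points, row.names = FALSE)
  cat(sprintf("  per-pixel maximum count rate (through-origin slope): %.3g\n",
              x$slope_fit$slope))
  invisible(x)
}

#' Through-origin slope of maximum count rate versus pixel count
#'
#' Least-squares line through the origin, `max_rate = slope * n_pixel`;
#' the slope is the maximum count rate per pixel.
#'
#' @param points Data frame with columns `n_pixel` and `max_rate` (>= 1
#'   row; a single point determines the slope exactly).
#' @return An object of class `slope_fit`: list with `slope`, `points`,
#'   `residuals`.
#' @export
#' @examples
#' fit_pixel_slope(data.frame(n_pixel = c(1, 10), max_rate = c(0.31, 3.1)))
fit_pixel_slope <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("n_pixel", "max_rate") %in% names(points)))
  if (nrow(points) < 1L)
    stop("`points` must contain at least one point", call. = FALSE)
  x <- points$n_pixel
  y <- points$max_rate
  slope <- sum(x * y) / sum(x * x)
  structure(list(slope = slope, points = points,
                 residuals = y - slope * x),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope = %.4g (%d points, RMS residual %.3g)\n",
              x$slope, nrow(x$points), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Rebin a histogram to a coarser time resolution
#'
#' Sums adjacent groups of `factor` bins; the new bin width is
#' `factor * tres_ns`.  A trailing partial group is summed into a final
#' (shorter-coverage) bin, so total counts are conserved exactly.
#'
#' @param hist A [tcspc_histogram()].
#' @param factor Positive integer rebinning factor.
#' @return A [tcspc_histogram()] with coarser bins.
#' @export
rebin_histogram <- function(hist, factor) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  check_count(factor, "factor", lower = 1)
  if (factor == 1L) return(hist)
  grp <- (seq_along(hist$counts) - 1L) %/% as.integer(factor) + 1L
  counts <- as.vector(rowsum(hist$counts, grp))
  tcspc_histogram(counts, hist$tres_ns * factor, hist$tw_ns,
                  n_dropped = hist$n_dropped)
}

#' Accuracy versus time resolution (rebinning study)
#'
#' Simulates `n_rep` measurements at the detector's native (fine) time
#' resolution, then rebins each histogram so that the effective bin width
#' is `factor * tau0` for every factor in `tres_factors`, refits, and
#' computes delta-tau per factor.  This emulates resizing the time
#' resolution after acquisition: accuracy is roughly flat while the bin
#' width stays below about two lifetimes, and collapses once nearly all
#' signal photons share the first bin.
#'
#' @param tres_factors Increasing positive bin widths in units of the
#'   lifetime, e.g. `c(0.1, 0.5, 1, 2, 4, 6)`.
#' @param rate Mean photons per window for the base simulations.
#' @param pulse,fluor,noise Simulation models.
#' @param config Base [detector_config()] (fine `tres_ns`).
#' @param n_rep Replicates; default 50.
#' @param seed Optional RNG seed.
#' @return An object of class `resolution_scan`: list with `table` (data
#'   frame `tres_factor`, `tres_ns`, `rebin_factor`, `delta_tau`, `n_ok`,
#'   `n_fail`) and `tau0_ns`.
#' @export
scan_resolution <- function(tres_factors, rate, pulse = laser_pulse(),
                            fluor = fluorophore(), noise = noise_model(),
                            config = detector_config(), n_rep = 50,
                            seed = NULL) {
  if (length(tres_factors) < 1L || any(tres_factors <= 0) ||
      any(diff(tres_factors) <= 0))
    stop("`tres_factors` must be positive and strictly increasing",
         call. = FALSE)
  check_count(n_rep, "n_rep", lower = 1)
  tau0 <- fluor$tau0_ns
  k <- pmax(1L, as.integer(round(tres_factors * tau0 / config$tres_ns)))
  if (any(k * config$tres_ns > config$tw_ns))
    stop("coarsest requested bin width exceeds the window duration",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  hists <- vector("list", n_rep)
  skip <- pipeline_skip_ns(pulse)
  for (i in seq_len(n_rep))
    hists[[i]] <- simulate_measurement(pulse, fluor, noise, rate,
                                       config)$histogram
  tab <- data.frame(tres_factor = tres_factors,
                    tres_ns = k * config$tres_ns, rebin_factor = k,
                    delta_tau = NA_real_, n_ok = 0L, n_fail = 0L)
  for (j in seq_along(k)) {
    taus <- numeric(0)
    n_fail <- 0L
    for (i in seq_len(n_rep)) {
      tau <- tryCatch(
        fit_lifetime(rebin_histogram(hists[[i]], k[j]),
                     skip_ns = skip)$tau_fit_ns,
        error = function(e) NA_real_)
      if (is.na(tau)) n_fail <- n_fail + 1L else taus <- c(taus, tau)
    }
    tab$delta_tau[j] <- if (length(taus)) relative_error(taus, tau0)
                        else NA_real_
    tab$n_ok[j] <- length(taus)
    tab$n_fail[j] <- n_fail
  }
  structure(list(table = tab, tau0_ns = tau0, rate = rate, n_rep = n_rep),
            class = "resolution_scan")
}

#' @export
print.resolution_scan <- function(x, ...) {
  cat(sprintf("<resolution_scan> tau0 = %.4g ns, rate %.3g/window, %d reps\n",
              x$tau0_ns, x$rate, x$n_rep))
  print(x$table, row.names = FALSE)
  invisible(x)
}

## expand one seed into n reproducible sub-seeds (< 2^31) so components of
## a composite experiment draw from independent streams.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}
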