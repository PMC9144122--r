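#' Z'-factor separation of two lifetime populations
#'
#' Assay-quality statistic for distinguishing two fluorophores by their
#' fitted lifetimes: `Z' = 1 - 3 * (sigma1 + sigma2) / |tau1 - tau2|`.
#' With both populations sharing a common relative spread `cv` (the form
#' used throughout the photon-budget analysis), `sigma_i = cv * tau_i` and
#' `Z' = 1 - (tau1 + tau2) * 3 * cv / |tau1 - tau2|`.  A second,
#' population-specific `cv2` may be supplied to generalise.
#'
#' `Z' >= 0.5` is the conventional bar for an excellent assay.
#'
#' @param tau1,tau2 Mean fitted lifetimes of the two populations (ns,
#'   `tau1 != tau2`).
#' @param cv Coefficient of variation (>= 0), shared by both populations
#'   unless `cv2` is given.
#' @param cv2 Optional coefficient of variation of population 2.
#' @return The Z' factor (<= 1; can be negative for overlapping
#'   populations).
#' @export
#' @examples
#' z_prime(10.6, 4.1, cv = 1 / sqrt(184))  # ~0.5
z_prime <- function(tau1, tau2, cv, cv2 = NULL) {
  check_scalar(tau1, "tau1", lower = 0, strict = TRUE)
  check_scalar(tau2, "tau2", lower = 0, strict = TRUE)
  check_scalar(cv, "cv", lower = 0, strict = FALSE)
  if (tau1 == tau2)
    stop("`tau1` and `tau2` must differ", call. = FALSE)
  if (is.null(cv2)) cv2 <- cv else check_scalar(cv2, "cv2", lower = 0)
  1 - 3 * (cv * tau1 + cv2 * tau2) / abs(tau1 - tau2)
}

#' Photon budget for a target Z'-factor
#'
#' Combines the Z'-factor with the Poisson precision law `cv ~ 1/sqrt(Nc)`
#' and solves for the photon counts needed to separate two lifetimes:
#' `Nc = [3 / (1 - Z') * (1 + r) / (1 - r)]^2`, with `r = tau2 / tau1 < 1`.
#'
#' The exact value is returned alongside an integer report; by default the
#' nearest integer, or the ceiling in `"ceiling"` mode (counts being a
#' requirement).
#'
#' @param z_prime Target Z' factor (`0 <= z_prime < 1`).
#' @param tau1,tau2 The two lifetimes (ns, `tau1 > tau2 > 0`); alternatively
#'   supply `ratio` directly.
#' @param ratio Lifetime ratio `tau2 / tau1` in (0, 1); overrides
#'   `tau1`/`tau2`.
#' @param mode `"nearest"` (default) or `"ceiling"` rounding of the
#'   reported count.
#' @return A list with `nc` (integer report) and `nc_exact`.
#' @export
#' @examples
#' required_counts(0.5, 10.6, 4.1)$nc   # 184
#' required_counts(0.5, ratio = 0.25)$nc  # 100
required_counts <- function(z_prime, tau1 = NULL, tau2 = NULL, ratio = NULL,
                            mode = c("nearest", "ceiling")) {
  mode <- match.arg(mode)
  check_scalar(z_prime, "z_prime", lower = 0, strict = FALSE)
  if (z_prime >= 1)
    stop("`z_prime` must be < 1", call. = FALSE)
  if (is.null(ratio)) {
    check_scalar(tau1, "tau1", lower = 0, strict = TRUE)
    check_scalar(tau2, "tau2", lower = 0, strict = TRUE)
    if (tau2 >= tau1)
      stop("`tau1` must exceed `tau2` (or supply `ratio` < 1)", call. = FALSE)
    ratio <- tau2 / tau1
  } else {
    check_scalar(ratio, "ratio", lower = 0, strict = FALSE)
    if (ratio >= 1) stop("`ratio` must be < 1", call. = FALSE)
  }
  nc_exact <- (3 / (1 - z_prime) * (1 + ratio) / (1 - ratio))^2
  nc <- if (mode == "nearest") round(nc_exact) else ceiling(nc_exact)
  list(nc = as.integer(nc), nc_exact = nc_exact)
}

#' Poisson precision law
#'
#' Approximate coefficient of variation of the fitted lifetime from the
#' number of detected photons: `cv ~ 1 / sqrt(Nc)`.
#'
#' @param n_counts Photon counts (>= 1).
#' @return The approximate cv.
#' @export
#' @examples
#' cv_from_counts(1000)  # 0.0316
cv_from_counts <- function(n_counts) {
  check_scalar(n_counts, "n_counts", lower = 1, strict = FALSE)
  1 / sqrt(n_counts)
}

#' Fraction of emitted photons captured by a finite window
#'
#' For a single-exponential decay, the proportion of all emitted photons
#' arriving within a window of duration `dtw_ns` is
#' `P = 1 - exp(-dtw / tau)`.  A window of 7 lifetimes captures 99.9% --
#' the design rule for the minimum window duration.
#'
#' @param dtw_ns Window duration(s) in ns (>= 0); vectorised.
#' @param tau_ns Lifetime in ns (> 0).
#' @return The capture fraction in \[0, 1).
#' @export
#' @examples
#' window_capture_fraction(7 * 5, 5)  # 0.999
window_capture_fraction <- function(dtw_ns, tau_ns) {
  if (!is.numeric(dtw_ns) || any(!is.finite(dtw_ns)) || any(dtw_ns < 0))
    stop("`dtw_ns` must be finite and >= 0", call. = FALSE)
  check_scalar(tau_ns, "tau_ns", lower = 0, strict = TRUE)
  1 - exp(-dtw_ns / tau_ns)
}

#' Count rate from total counts and number of windows
#'
#' `<Nc>_w = Nc / nw`, the mean detected photons per measurement window.
#'
#' @param n_counts Total photon counts (>= 0).
#' @param nw Number of measurement windows (>= 1).
#' @return The count rate in photons per window.
#' @export
count_rate <- function(n_counts, nw) {
  check_scalar(n_counts, "n_counts", lower = 0, strict = FALSE)
  check_count(nw, "nw", lower = 1)
  n_counts / nw
}

#' Total measurement time for a photon-count target
#'
#' The number of windows needed is `Nc / <Nc>_w` and each window lasts
#' `window_factor * tau`, so
#' `ttot = (n_counts_target * window_factor * tau) / (per_pixel_rate *
#' n_pixel)`.  With the defaults (1000 counts, 0.31 counts/window/pixel,
#' 7-lifetime windows) this is `7000 * tau / (0.31 * n_pixel)`.
#'
#' @param tau_ns Lifetime in ns (> 0).
#' @param n_pixel Number of pixels (> 0).
#' @param n_counts_target Photon counts to acquire (> 0); default 1000.
#' @param per_pixel_rate Maximum pile-up-free count rate per pixel
#'   (photons/window/pixel, > 0); default 0.31, as recovered by
#'   [max_rate_vs_pixels()].
#' @param window_factor Window duration in lifetimes (> 0); default 7
#'   (99.9% photon capture).
#' @return Total measurement time in seconds.
#' @export
#' @examples
#' total_measurement_time(10, 30) * 1e6   # 7.53 us
#' total_measurement_time(10, 300) * 1e6  # 0.753 us
total_measurement_time <- function(tau_ns, n_pixel, n_counts_target = 1000,
                                   per_pixel_rate = 0.31, window_factor = 7) {
  check_scalar(tau_ns, "tau_ns", lower = 0, strict = TRUE)
  check_scalar(n_pixel, "n_pixel", lower = 0, strict = TRUE)
  check_scalar(n_counts_target, "n_counts_target", lower = 0, strict = TRUE)
  check_scalar(per_pixel_rate, "per_pixel_rate", lower = 0, strict = TRUE)
  check_scalar(window_factor, "window_factor", lower = 0, strict = TRUE)
  (n_counts_target * window_factor * tau_ns * 1e-9) /
    (per_pixel_rate * n_pixel)
}

#' Detector data rate
#'
#' Assuming per-window pixel counts are summed into a single value, each
#' time bin carries `log2(n_pixel + 1)` bits, and with the time resolution
#' set to `tres_factor` lifetimes the continuous-readout data rate is
#' `log2(n_pixel + 1) / (tres_factor * tau)`.  A time resolution of four
#' lifetimes still supports ~10% lifetime accuracy, which is the default.
#'
#' @param n_pixel Number of pixels (>= 1).
#' @param tau_ns Lifetime in ns (> 0).
#' @param tres_factor Time resolution in lifetimes (> 0); default 4.
#' @return Data rate in bit/s.
#' @export
#' @examples
#' data_rate(300, 3) / 1e6   # ~686 Mbit/s
#' data_rate(1000, 3) / 1e9  # ~0.83 Gbit/s
data_rate <- function(n_pixel, tau_ns, tres_factor = 4) {
  check_count(n_pixel, "n_pixel", lower = 1)
  check_scalar(tau_ns, "tau_ns", lower = 0, strict = TRUE)
  check_scalar(tres_factor, "tres_factor", lower = 0, strict = TRUE)
  log2(n_pixel + 1) / (tres_factor * tau_ns * 1e-9)
}

#' Full design report for one operating point
#'
#' Evaluates the complete chain of design quantities for a lifetime and a
#' pixel count: required photon budget for the requested Z' separation,
#' minimum window duration, total measurement time, and data rate.
#'
#' @param tau_ns Lifetime in ns.
#' @param n_pixel Number of pixels.
#' @param z_prime Target Z' (with `ratio`) used for the photon budget;
#'   default 0.5.
#' @param ratio Lifetime ratio `tau2/tau1` of the two populations to
#'   separate; default 0.25.
#' @param n_counts_target Photon counts used for time/rate planning;
#'   default 1000.
#' @param per_pixel_rate Maximum pile-up-free count rate per pixel;
#'   default 0.31.
#' @param window_factor Window duration in lifetimes; default 7.
#' @param tres_factor Time resolution in lifetimes for the data rate;
#'   default 4.
#' @return A list of class `design_point` with all inputs and the derived
#'   `nc_required`, `cv_at_target`, `dtw_ns`, `ttot_s`, `drate_bit_s`.
#' @export
design_report <- function(tau_ns, n_pixel, z_prime = 0.5, ratio = 0.25,
                          n_counts_target = 1000, per_pixel_rate = 0.31,
                          window_factor = 7, tres_factor = 4) {
  nc <- required_counts(z_prime, ratio = ratio)
  out <- list(tau_ns = tau_ns, n_pixel = n_pixel, z_prime = z_prime,
              ratio = ratio, n_counts_target = n_counts_target,
              per_pixel_rate = per_pixel_rate,
              window_factor = window_factor, tres_factor = tres_factor,
              nc_required = nc$nc, nc_required_exact = nc$nc_exact,
              cv_at_target = cv_from_counts(n_counts_target),
              dtw_ns = window_factor * tau_ns,
              capture_fraction = window_capture_fraction(
                window_factor * tau_ns, tau_ns),
              ttot_s = total_measurement_time(
                tau_ns, n_pixel, n_counts_target, per_pixel_rate,
                window_factor),
              drate_bit_s = data_rate(n_pixel, tau_ns, tres_factor))
  class(out) <- "design_point"
  out
}

#' @export
print.design_point <- function(x, ...) {
  cat(sprintf("<design_point> tau = %.4g ns, %d pixels\n", x$tau_ns,
              as.integer(x$n_pixel)))
  cat(sprintf("  photon budget (Z' = %.2g, ratio %.2g): %d counts\n",
              x$z_prime, x$ratio, x$nc_required))
  cat(sprintf("  window: %.4g ns (captures %.1f%% of photons)\n",
              x$dtw_ns, 100 * x$capture_fraction))
  cat(sprintf("  total measurement time: %.4g us\n", x$ttot_s * 1e6))
  cat(sprintf("  data rate: %.4g Mbit/s\n", x$drate_bit_s / 1e6))
  invisible(x)
}
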