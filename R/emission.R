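#' Sample photon arrival times at the detector
#'
#' Draws `n` fluorescence-photon arrival times from the convolution of the
#' laser pulse shape with the single-exponential emission decay.  Each time
#' is the sum of three independent draws,
#' `Uniform(0, fwhm) + Exp(turnoff) + Exp(tau0)`, so the convolution is
#' exact (no gridding).  All times are >= 0, measured from the start of the
#' laser plateau.
#'
#' @param n Number of photons to draw (>= 0).
#' @param pulse A [laser_pulse()].
#' @param fluor A [fluorophore()].
#' @return Numeric vector of `n` arrival times in ns.
#' @seealso [arrival_density()] for the corresponding closed-form density.
#' @export
#' @examples
#' set.seed(1)
#' t <- sample_arrival_times(5, laser_pulse(), fluorophore(5))
sample_arrival_times <- function(n, pulse, fluor) {
  check_count(n, "n", lower = 0)
  stopifnot(inherits(pulse, "laser_pulse"), inherits(fluor, "fluorophore"))
  if (n == 0L) return(numeric(0))
  u <- if (pulse$fwhm_ns > 0) stats::runif(n, 0, pulse$fwhm_ns) else 0
  u + stats::rexp(n, rate = 1 / pulse$turnoff_ns) +
    stats::rexp(n, rate = 1 / fluor$tau0_ns)
}

#' Sample emitted-photon counts per measurement window
#'
#' Each excitation pulse induces a Poisson-distributed number of emitted
#' fluorescence photons; the mean is the count rate `<Nc>_w` that would be
#' detected without pile-up.
#'
#' @param mean_per_window Mean photons per window (>= 0).
#' @param nw Number of measurement windows (>= 1).
#' @return Integer vector of length `nw` with the photon count per window.
#' @export
#' @examples
#' set.seed(1)
#' sum(sample_window_counts(0.31, 1000))  # ~310 photons in total
sample_window_counts <- function(mean_per_window, nw) {
  check_scalar(mean_per_window, "mean_per_window", lower = 0, strict = FALSE)
  check_count(nw, "nw", lower = 1)
  stats::rpois(nw, mean_per_window)
}

#' Sample background (noise) events
#'
#' Per window the number of background events is Poisson with mean
#' `noise$noise_per_window`, and each event time is uniform on
#' `[0, tw_ns)`.
#'
#' @param noise A [noise_model()].
#' @param tw_ns Window duration in ns (> 0).
#' @param nw Number of windows (>= 1).
#' @return A data frame with columns `window` (integer index, 1..nw) and
#'   `time_ns`.
#' @export
sample_noise_times <- function(noise, tw_ns, nw) {
  stopifnot(inherits(noise, "noise_model"))
  check_scalar(tw_ns, "tw_ns", lower = 0, strict = TRUE)
  check_count(nw, "nw", lower = 1)
  k <- stats::rpois(nw, noise$noise_per_window)
  window <- rep.int(seq_len(nw), k)
  data.frame(window = window,
             time_ns = stats::runif(length(window), 0, tw_ns))
}

#' Closed-form arrival-time density and distribution function
#'
#' Density `f(t)` and CDF `F(t)` of a fluorescence-photon arrival time,
#' i.e. of `Uniform(0, w) + Exp(a) + Exp(b)` with `w` the pulse plateau
#' width, `a` the turn-off constant and `b` the lifetime.  The two
#' exponential stages give a hypoexponential density
#' `f2(t) = (exp(-t/b) - exp(-t/a)) / (b - a)` (with the `a == b` limit
#' `t/a^2 exp(-t/a)`), which is then averaged over the plateau.
#'
#' These are the reference curves the Monte Carlo sampler is validated
#' against, and the ingredients of [detected_density()].
#'
#' @param t Vector of times in ns (values < 0 give 0).
#' @param pulse A [laser_pulse()].
#' @param fluor A [fluorophore()].
#' @return Numeric vector of density (CDF) values.
#' @export
arrival_density <- function(t, pulse, fluor) {
  stopifnot(inherits(pulse, "laser_pulse"), inherits(fluor, "fluorophore"))
  w <- pulse$fwhm_ns
  a <- pulse$turnoff_ns
  b <- fluor$tau0_ns
  if (w == 0) return(hypo_pdf(t, a, b))
  (hypo_cdf(t, a, b) - hypo_cdf(t - w, a, b)) / w
}

#' @rdname arrival_density
#' @export
arrival_cdf <- function(t, pulse, fluor) {
  stopifnot(inherits(pulse, "laser_pulse"), inherits(fluor, "fluorophore"))
  w <- pulse$fwhm_ns
  a <- pulse$turnoff_ns
  b <- fluor$tau0_ns
  if (w == 0) return(hypo_cdf(t, a, b))
  (hypo_cdf_int(t, a, b) - hypo_cdf_int(t - w, a, b)) / w
}

## hypoexponential Exp(a) + Exp(b): pdf, cdf, and integral of the cdf.
## Near-equal constants switch to the Gamma(2) limit for stability.

hypo_pdf <- function(t, a, b) {
  out <- numeric(length(t))
  p <- t > 0
  tp <- t[p]
  if (abs(a - b) < 1e-9 * max(a, b)) {
    out[p] <- tp / a^2 * exp(-tp / a)
  } else {
    out[p] <- (exp(-tp / b) - exp(-tp / a)) / (b - a)
  }
  out
}

hypo_cdf <- function(t, a, b) {
  out <- numeric(length(t))
  p <- t > 0
  tp <- t[p]
  if (abs(a - b) < 1e-9 * max(a, b)) {
    out[p] <- 1 - (1 + tp / a) * exp(-tp / a)
  } else {
    out[p] <- 1 - (b * exp(-tp / b) - a * exp(-tp / a)) / (b - a)
  }
  out
}

## G(s) = integral_0^s hypo_cdf(v) dv, used to average the cdf over the
## rectangular plateau.
hypo_cdf_int <- function(t, a, b) {
  out <- numeric(length(t))
  p <- t > 0
  s <- t[p]
  if (abs(a - b) < 1e-9 * max(a, b)) {
    out[p] <- s - 2 * a * (1 - exp(-s / a)) + s * exp(-s / a)
  } else {
    out[p] <- s - (b^2 * (1 - exp(-s / b)) - a^2 * (1 - exp(-s / a))) / (b - a)
  }
  out
}
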