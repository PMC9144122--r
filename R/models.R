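#' Excitation laser pulse model
#'
#' The pulse is modelled as a rectangular plateau of width `fwhm_ns` followed
#' by an exponential falling edge ("turn-off") with time constant
#' `turnoff_ns`.  An excitation time is then the sum of two independent
#' draws, `Uniform(0, fwhm_ns) + Exp(turnoff_ns)`, which makes the
#' convolution of the pulse with the fluorescence decay exact by summation of
#' random variates -- no gridded convolution is needed during sampling.
#'
#' The turn-off time is interpreted as the time *constant* of the exponential
#' falling edge (not a 90--10 fall time).  `fwhm_ns = 0` degenerates to a
#' pulse that is instantaneous up to its exponential tail.
#'
#' @param fwhm_ns Full width at half maximum of the pulse plateau in ns
#'   (>= 0).  Default 1.25 ns.
#' @param turnoff_ns Time constant of the exponential falling edge in ns
#'   (> 0).  Default 0.5 ns.
#' @return An object of class `laser_pulse`.
#' @seealso [fluorophore()], [sample_arrival_times()]
#' @export
#' @examples
#' laser_pulse()
#' laser_pulse(fwhm_ns = 0, turnoff_ns = 1e-6)  # near-instantaneous pulse
laser_pulse <- function(fwhm_ns = 1.25, turnoff_ns = 0.5) {
  check_scalar(fwhm_ns, "fwhm_ns", lower = 0, strict = FALSE)
  check_scalar(turnoff_ns, "turnoff_ns", lower = 0, strict = TRUE)
  structure(list(fwhm_ns = fwhm_ns, turnoff_ns = turnoff_ns),
            class = "laser_pulse")
}

#' Fluorophore model
#'
#' A fluorophore with single-exponential emission decay
#' `I(t) = I0 * exp(-t / tau0)`, characterised entirely by its intrinsic
#' lifetime `tau0_ns`.
#'
#' @param tau0_ns Intrinsic fluorescence lifetime in ns (> 0).  Default 5 ns,
#'   a typical organic-dye lifetime.
#' @return An object of class `fluorophore`.
#' @export
#' @examples
#' fluorophore(tau0_ns = 5)
fluorophore <- function(tau0_ns = 5) {
  check_scalar(tau0_ns, "tau0_ns", lower = 0, strict = TRUE)
  structure(list(tau0_ns = tau0_ns), class = "fluorophore")
}

#' Background (noise) event model
#'
#' Background events -- dark counts and stray light -- occur at a mean rate
#' of `noise_per_window` events per measurement window, Poisson distributed
#' over windows and uniformly distributed in time within each window.
#'
#' @param noise_per_window Mean number of background events per measurement
#'   window (>= 0).  Default 0.01.
#' @return An object of class `noise_model`.
#' @export
#' @examples
#' noise_model(0)      # noise-free
#' noise_model(0.01)
noise_model <- function(noise_per_window = 0.01) {
  check_scalar(noise_per_window, "noise_per_window", lower = 0, strict = FALSE)
  structure(list(noise_per_window = noise_per_window), class = "noise_model")
}

#' SPAD array detector configuration
#'
#' Geometry and timing of the detector: number of pixels, histogram bin
#' width (time resolution), measurement-window duration, number of windows
#' per measurement, and whether the one-photon-per-pixel-per-window pile-up
#' mechanism is active.
#'
#' Defaults follow a 312.5 ps time resolution, 30,000 windows per
#' measurement, and a window duration of 1.28 us (the sensitive on-phase of
#' the detector between readouts).  Disabling `pileup` yields an idealised
#' detector that registers every arriving photon; this is the reference
#' against which pile-up bias is measured.
#'
#' @param n_pixel Number of SPAD pixels (>= 1).
#' @param tres_ns Histogram bin width in ns (> 0).  Default 0.3125.
#' @param tw_ns Measurement-window duration in ns (>= `tres_ns`).
#'   Default 1280.
#' @param nw Number of measurement windows per measurement (>= 1).
#'   Default 30000.
#' @param pileup Logical; if `TRUE` (default) each pixel registers at most
#'   one photon (the earliest) per window.
#' @return An object of class `detector_config`.
#' @export
#' @examples
#' detector_config(n_pixel = 100)
#' detector_config(n_pixel = 1, pileup = FALSE)
detector_config <- function(n_pixel = 1, tres_ns = 0.3125, tw_ns = 1280,
                            nw = 30000, pileup = TRUE) {
  check_count(n_pixel, "n_pixel", lower = 1)
  check_scalar(tres_ns, "tres_ns", lower = 0, strict = TRUE)
  check_scalar(tw_ns, "tw_ns", lower = 0, strict = TRUE)
  check_count(nw, "nw", lower = 1)
  if (tw_ns < tres_ns)
    stop("`tw_ns` must be >= `tres_ns`", call. = FALSE)
  if (!is.logical(pileup) || length(pileup) != 1L || is.na(pileup))
    stop("`pileup` must be TRUE or FALSE", call. = FALSE)
  structure(list(n_pixel = as.integer(n_pixel), tres_ns = tres_ns,
                 tw_ns = tw_ns, nw = as.integer(nw), pileup = pileup),
            class = "detector_config")
}

#' @export
print.laser_pulse <- function(x, ...) {
  cat(sprintf("<laser_pulse> plateau FWHM %.4g ns, turn-off constant %.4g ns\n",
              x$fwhm_ns, x$turnoff_ns))
  invisible(x)
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf("<fluorophore> tau0 = %.4g ns (single-exponential decay)\n",
              x$tau0_ns))
  invisible(x)
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %.4g background events/window (uniform in window)\n",
              x$noise_per_window))
  invisible(x)
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "<detector_config> %d pixel(s), tres %.4g ns, tw %.4g ns, nw %d, pile-up %s\n",
    x$n_pixel, x$tres_ns, x$tw_ns, x$nw, if (x$pileup) "on" else "off"))
  invisible(x)
}

## argument validation helpers ------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x))
    stop(sprintf("`%s` must be a single whole number", name), call. = FALSE)
  if (x < lower)
    stop(sprintf("`%s` must be >= %d", name, lower), call. = FALSE)
  invisible(x)
}
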