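#' Assign events to detector pixels
#'
#' Events are spread over the array statistically: each event independently
#' lands on a uniformly chosen pixel (homogeneous illumination).
#'
#' @param times Vector of event times (only its length is used).
#' @param n_pixel Number of pixels (>= 1).
#' @return Integer vector of pixel labels in `1..n_pixel`, one per event.
#' @export
assign_pixels <- function(times, n_pixel) {
  check_count(n_pixel, "n_pixel", lower = 1)
  if (length(times) == 0L) return(integer(0))
  sample.int(n_pixel, length(times), replace = TRUE)
}

#' Apply the one-photon-per-pixel-per-window pile-up rule
#'
#' A SPAD pixel can register only one photon per measurement window: of all
#' events falling on the same pixel in the same window, only the earliest
#' ("fastest") is detected.  With `pileup_enabled = FALSE` the detector is
#' idealised and every event is kept -- the reference case in which the
#' fitted lifetime stays unbiased at any count rate.
#'
#' Ties (identical times on one pixel) keep the event that was generated
#' first.
#'
#' @param events A data frame with columns `window`, `pixel`, `time_ns`.
#' @param pileup_enabled Logical.
#' @return The detected subset of `events`, in the original row order.
#' @export
apply_pileup <- function(events, pileup_enabled = TRUE) {
  stopifnot(is.data.frame(events),
            all(c("window", "pixel", "time_ns") %in% names(events)))
  if (!pileup_enabled || nrow(events) == 0L) return(events)
  keep <- first_photon_idx(events$window, events$pixel, events$time_ns)
  events[keep, , drop = FALSE]
}

## indices of the earliest event per (window, pixel), in generation order.
## Stable radix sort on time makes ties resolve to the first-generated event.
first_photon_idx <- function(window, pixel, time_ns) {
  if (length(time_ns) == 0L) return(integer(0))
  o <- order(time_ns, method = "radix")
  key <- (window[o] - 1) * (max(pixel) + 1) + pixel[o]
  sort(o[!duplicated(key)])
}

#' Build an arrival-time histogram
#'
#' Quantizes detected times to the detector's time resolution: an event at
#' time `t` falls in bin `floor(t / tres_ns)`, with half-open bins
#' `[k*tres, (k+1)*tres)`.  Events at `t >= tw_ns` fall outside the
#' measurement window; they are dropped and reported in `n_dropped`.
#'
#' @param times Vector of detected times in ns.
#' @param config A [detector_config()].
#' @return A `tcspc_histogram` object; see [tcspc_histogram()].
#' @export
quantize_and_histogram <- function(times, config) {
  stopifnot(inherits(config, "detector_config"))
  n_bins <- as.integer(ceiling(config$tw_ns / config$tres_ns))
  inw <- times < config$tw_ns & times >= 0
  bins <- floor(times[inw] / config$tres_ns)
  counts <- tabulate(as.integer(bins) + 1L, nbins = n_bins)
  tcspc_histogram(counts, config$tres_ns, config$tw_ns,
                  n_dropped = sum(!inw))
}

#' TCSPC arrival-time histogram
#'
#' The central exchange object: binned photon arrival times with bin width
#' `tres_ns` on `[0, tw_ns)`.  `sum(counts)` equals the number of in-window
#' detected events; events beyond the window are tallied in `n_dropped`.
#'
#' @param counts Non-negative numeric vector of per-bin counts.
#' @param tres_ns Bin width in ns (> 0).
#' @param tw_ns Window duration in ns.
#' @param n_dropped Number of events at `t >= tw_ns` (not in `counts`).
#' @return An object of class `tcspc_histogram` with fields `counts`,
#'   `tres_ns`, `tw_ns`, `n_dropped`.
#' @export
tcspc_histogram <- function(counts, tres_ns, tw_ns, n_dropped = 0) {
  check_scalar(tres_ns, "tres_ns", lower = 0, strict = TRUE)
  if (any(counts < 0)) stop("histogram counts must be >= 0", call. = FALSE)
  structure(list(counts = as.numeric(counts), tres_ns = tres_ns,
                 tw_ns = tw_ns, n_dropped = n_dropped),
            class = "tcspc_histogram")
}

#' @export
print.tcspc_histogram <- function(x, ...) {
  cat(sprintf(
    "<tcspc_histogram> %d bins x %.4g ns (window %.4g ns), %d counts, %d dropped\n",
    length(x$counts), x$tres_ns, x$tw_ns, round(sum(x$counts)), x$n_dropped))
  invisible(x)
}

#' Bin start times of a histogram
#'
#' @param hist A [tcspc_histogram()].
#' @return Numeric vector of left bin edges in ns.
#' @export
bin_starts <- function(hist) {
  stopifnot(inherits(hist, "tcspc_histogram"))
  (seq_along(hist$counts) - 1) * hist$tres_ns
}

#' @export
as.data.frame.tcspc_histogram <- function(x, ...) {
  data.frame(bin_start_ns = bin_starts(x), count = x$counts)
}

#' Simulate one complete TCSPC measurement
#'
#' Composes the full Monte Carlo pipeline: Poisson photon counts per window,
#' arrival times from the pulse-decay convolution, background events,
#' uniform spreading over pixels, the one-photon-per-pixel-per-window
#' pile-up rule, and quantization into the arrival-time histogram.
#'
#' @param pulse A [laser_pulse()].
#' @param fluor A [fluorophore()].
#' @param noise A [noise_model()]; default no noise.
#' @param rate Mean fluorescence photons per window `<Nc>_w` (>= 0) -- the
#'   count rate that would be detected without pile-up.
#' @param config A [detector_config()].
#' @param keep_times If `TRUE`, the detected times are returned as well
#'   (memory permitting).
#' @return A list of class `tcspc_measurement` with elements `histogram`
#'   (a [tcspc_histogram()]), `n_arrived` (fluorescence photons generated),
#'   `n_noise`, `n_detected` (events surviving pile-up) and, when requested,
#'   `times_detected`.
#' @export
#' @examples
#' set.seed(42)
#' m <- simulate_measurement(laser_pulse(), fluorophore(5), noise_model(0),
#'                           rate = 0.033, config = detector_config(n_pixel = 100))
#' m$histogram
simulate_measurement <- function(pulse, fluor, noise = noise_model(0), rate,
                                 config, keep_times = FALSE) {
  stopifnot(inherits(pulse, "laser_pulse"), inherits(fluor, "fluorophore"),
            inherits(noise, "noise_model"), inherits(config, "detector_config"))
  check_scalar(rate, "rate", lower = 0, strict = FALSE)

  nph <- sample_window_counts(rate, config$nw)
  n_arrived <- sum(nph)
  t_f <- sample_arrival_times(n_arrived, pulse, fluor)
  w_f <- rep.int(seq_len(config$nw), nph)

  ns <- sample_noise_times(noise, config$tw_ns, config$nw)
  w_all <- c(w_f, ns$window)
  t_all <- c(t_f, ns$time_ns)

  px <- assign_pixels(t_all, config$n_pixel)
  if (config$pileup && !keep_times) {
    ## fast path: pile-up resolved at bin resolution.  The earliest event
    ## per (window, pixel) lands in that pixel's earliest occupied bin, so
    ## the histogram is identical to the exact-time computation; only the
    ## (unreturned) sub-bin times differ.  Integer keys keep the radix
    ## sort cheap.
    n_bins <- as.integer(ceiling(config$tw_ns / config$tres_ns))
    if (length(t_all)) {
      bins <- as.integer(t_all %/% config$tres_ns)
      key <- (w_all - 1L) * config$n_pixel + px
      o <- order(key, bins, method = "radix")
      ko <- key[o]
      n_ev <- length(ko)
      first <- if (n_ev > 1L)
        c(TRUE, ko[2:n_ev] != ko[1:(n_ev - 1L)]) else TRUE
      det_bins <- bins[o][first]
    } else {
      det_bins <- integer(0)
    }
    inw <- det_bins < n_bins
    hist <- tcspc_histogram(tabulate(det_bins[inw] + 1L, nbins = n_bins),
                            config$tres_ns, config$tw_ns,
                            n_dropped = sum(!inw))
    n_detected <- length(det_bins)
  } else {
    if (config$pileup) {
      keep <- first_photon_idx(w_all, px, t_all)
      t_det <- t_all[keep]
    } else {
      t_det <- t_all
    }
    hist <- quantize_and_histogram(t_det, config)
    n_detected <- length(t_det)
  }

  out <- list(histogram = hist, n_arrived = n_arrived,
              n_noise = nrow(ns), n_detected = n_detected,
              rate = rate, config = config)
  if (keep_times) out$times_detected <- t_det
  class(out) <- "tcspc_measurement"
  out
}

#' @export
print.tcspc_measurement <- function(x, ...) {
  cat(sprintf(
    "<tcspc_measurement> rate %.4g/window: %d arrived (+%d noise), %d detected\n",
    x$rate, x$n_arrived, x$n_noise, x$n_detected))
  print(x$histogram)
  invisible(x)
}

#' Closed-form density of detected (first-photon) events
#'
#' For a Poisson photon stream of mean `rate` per window, thinned uniformly
#' onto `n_pixel` pixels with each pixel keeping only its earliest event,
#' the expected detected-event intensity per window is
#' `rate * f(t) * exp(-(rate / n_pixel) * F(t))`, with `f` and `F` the
#' arrival-time density and CDF.  Its integral over all t is
#' `n_pixel * (1 - exp(-rate / n_pixel))`, the expected detected count per
#' window.  This is the exact reference curve for the pile-up mechanism:
#' simulated detected-time histograms must match its shape.
#'
#' @param t Vector of times in ns.
#' @param rate Mean photons per window (>= 0).
#' @param n_pixel Number of pixels (>= 1).
#' @param pulse A [laser_pulse()].
#' @param fluor A [fluorophore()].
#' @return Detected-event intensity per window at `t` (units 1/ns).
#' @export
detected_density <- function(t, rate, n_pixel, pulse, fluor) {
  check_scalar(rate, "rate", lower = 0, strict = FALSE)
  check_count(n_pixel, "n_pixel", lower = 1)
  rate * arrival_density(t, pulse, fluor) *
    exp(-(rate / n_pixel) * arrival_cdf(t, pulse, fluor))
}
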