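---
title: "Simulating SPAD-array lifetime measurements: models, parameters, design"
author: "spadsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SPAD-array lifetime measurements: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadsim)
```

## The measurement being simulated

Time-correlated single-photon counting (TCSPC) determines a fluorescence
lifetime by exciting a fluorophore with a short laser pulse, timing the
arrival of single emitted photons at a single-photon detector, and
histogramming those arrival times over many excitation cycles
("measurement windows").  The histogram follows the convolution of the
excitation pulse with the single-exponential emission decay
$I(t) = I_0\,e^{-t/\tau}$, and a nonlinear least-squares fit of that decay
yields the lifetime estimate $\tau_{\mathrm{fit}}$.

A single-photon avalanche diode (SPAD) pixel can register at most one
photon per window: once it fires it stays blind until it is re-armed for
the next cycle.  When the mean photon rate per window approaches the number
of pixels, only the *fastest* photons are registered, the histogram is
compressed toward early times, and the fitted lifetime is biased low.
This "first-photon" distortion is pile-up.  An $N$-pixel SPAD array
relaxes the limit roughly $N$-fold, which is what makes microsecond-scale
lifetime measurements conceivable.  `spadsim` simulates this pipeline
photon by photon and provides the closed-form calculators needed to size
such a measurement.

## The Monte Carlo model

One simulated measurement (`simulate_measurement()`) composes five stages:

1. **Counts per window.**  Each excitation pulse yields a Poisson number of
   emitted photons with mean `rate` — the count rate
   $\langle N_c\rangle_w$ that *would* be detected without pile-up.
2. **Arrival times.**  Each photon's arrival time is the sum of three
   independent draws, $U(0, \mathrm{fwhm}) + \mathrm{Exp}(\mathrm{turnoff})
   + \mathrm{Exp}(\tau_0)$: a rectangular pulse plateau, the exponential
   falling edge of the laser, and the emission decay.  Sampling sums of
   draws makes the triple convolution exact without any gridding; the
   matching closed-form density and CDF are exposed as
   `arrival_density()` / `arrival_cdf()`.
3. **Background.**  Dark counts and stray light are Poisson per window
   (`noise_per_window`) and uniform over the window duration.
4. **Detector.**  Every event lands on an independently, uniformly chosen
   pixel (homogeneous illumination).  With pile-up enabled, only the
   earliest event per pixel and window survives; ties keep the
   first-generated event.  Arrival times are then quantized into half-open
   bins of width `tres_ns`; events beyond the window are dropped and
   tallied separately.
5. **Estimation.**  `fit_lifetime()` fits $I_0 e^{-t/\tau}$ to the bin
   counts at bin centers by unweighted nonlinear least squares, from the
   decaying flank of the histogram to the end of the window, with a
   log-linear regression supplying starting values.

The exact detected-event intensity under this mechanism has the closed
form $\mu f(t)\, e^{-(\mu/N) F(t)}$ for mean rate $\mu$ and $N$ pixels
(`detected_density()`); its total mass is $N(1 - e^{-\mu/N})$.  The test
suite holds the simulated histograms to this curve at
Kolmogorov–Smirnov distance below 0.02.

## Parameters, defaults, and why

| parameter | default | meaning |
|---|---|---|
| `tau0_ns` | 5 | fluorophore lifetime; typical organic dye |
| `fwhm_ns` | 1.25 | laser plateau width |
| `turnoff_ns` | 0.5 | laser falling-edge time constant |
| `noise_per_window` | 0.01 | background events per window |
| `tres_ns` | 0.3125 | histogram bin width (312.5 ps class detector) |
| `tw_ns` | 1280 | window duration (detector on-phase) |
| `nw` | 30000 | windows per measurement |
| `n_pixel` | 1 | SPAD pixels |

Two defaults deserve comment.  The *pulse shape* is a modelling choice:
the plateau is taken rectangular and the "turn-off time" is read as the
exponential time constant of the falling edge — the simplest shape
consistent with a stated width and turn-off, and one that keeps sampling
exact.  The *window duration* defaults to 1.28&nbsp;µs, a realistic
sensitive on-phase for this detector class, rather than the design
minimum of $7\tau$: the time-resolution study rebins histograms up to bin
widths of $6\tau$ and needs many bins of mostly-background tail for that
question to be meaningful.  The background level (0.01 events/window) is a
plausible dark-count/stray-light magnitude for a cooled setup; it is a
configuration field precisely because real noise floors vary widely, and
several reported quantities (notably the self-calibrated accuracy
threshold below) depend on it.

## The fit range and the excitation transient

The exponential model does not describe the rising edge of the histogram,
so the fit must start after the peak.  Starting *immediately* after the
peak is, however, measurably biased: on the exact expected histogram
(no noise, no sampling) the laser's falling edge contaminates the first
nanoseconds after the peak and pulls the fitted lifetime up by about
2.3% for the default pulse.  The simulation pipeline therefore starts the
fit five turn-off constants after the peak (`pipeline_skip_ns()`), where
the residual transient is below 0.1%; with this guard the Monte Carlo
fits are unbiased at low count rate to within simulation error.
Standalone `fit_lifetime()` keeps the plain "one bin after the maximum"
default (`skip_ns = 0`) so the bias–range trade-off stays in the caller's
hands.

Zero-count bins inside the range are retained, and at least two populated
bins are required — with very coarse binning the decay can collapse into
a single bin, at which point no line fit is possible.

## Precision, accuracy, and what unweighted LS costs

Precision is the coefficient of variation over replicate measurements,
$c_v = \sigma / \langle\tau_{\mathrm{fit}}\rangle$ (sample SD, arithmetic
mean); accuracy is the mean absolute relative error
$\delta_\tau = \langle|\tau_{\mathrm{fit}} - \tau_0|/\tau_0\rangle$.
Both are roughly log-normal over repeated series, so representative
values aggregate as geometric means (`aggregate_geometric()`).

Poisson statistics make $c_v \propto 1/\sqrt{N_c}$, independent of the
absolute lifetime; the test suite verifies the log–log slope of
$-0.5 \pm 0.05$.  The *constant* in front is a property of the estimator:
unweighted least squares on Poisson histograms is statistically
inefficient, and under the default configuration the measured constant is
roughly 2–2.5 rather than 1.  The analytic planning helper
`cv_from_counts()` deliberately returns the idealised $1/\sqrt{N_c}$ —
design numbers derived from it (photon budgets, the 3.16% at 1000
counts) refer to an efficient estimator, while simulated $c_v$ values
include the estimator's real spread.

## The pile-up scan and its self-calibrated threshold

`scan_count_rate()` sweeps the count rate at fixed `nw` and records
$\delta_\tau$: accuracy first improves with rate (more photons), then
degrades as the first-photon bias takes over, giving a U-shaped curve.
`find_max_count_rate()` locates, on the rising branch, the rate at which
$\delta_\tau$ crosses an accuracy threshold, interpolating log-linearly
between the bracketing grid points.

The threshold is not hard-coded.  It is re-measured, per study, as the
pile-up-free $\delta_\tau$ at a reference photon count of 1000
(`calibrate_accuracy_threshold()`), under the same pulse, noise, fitting
and windowing conditions as the scan itself.  An absolute percentage
would silently embed one particular noise floor and estimator; the
self-calibrated threshold keeps the operating point — "the accuracy you
would have at 1000 counts" — meaningful under any configuration.  A fixed
`threshold` override exists for reproducing a specific absolute level.

`max_rate_vs_pixels()` repeats the scan for pixel counts
$\{1, 3, 10, 30, 100\}$ and fits `max_rate` against `n_pixel` through the
origin; through-origin is the natural model because a single ratio — the
maximum count rate *per pixel* — is the quantity of interest.  Under the
default configuration this slope comes out near 0.31 photons per window
per pixel, with the heaviest weight on the largest pixel counts.  The
default rate grid spans $0.05N$–$1.2N$ photons/window at 8 points per
decade: wide enough to bracket the crossing for any threshold the default
conditions produce, narrow enough that a five-pixel-count study with 30
replicates per point completes in a few minutes on one core.

## The time-resolution (rebinning) study

`scan_resolution()` simulates at the native bin width and then *rebins*
each histogram to effective widths of `tres_factors` × τ before
refitting, emulating a detector with a coarser time-to-digital converter.
Accuracy stays approximately flat while the bin width is below about two
lifetimes; once nearly the whole decay falls into the first bin, the
remaining bins carry mostly background and the fit degrades sharply.
Rebinning sums adjacent groups of bins exactly (a trailing partial group
goes into a final bin), so total counts are conserved for every factor.

## Design calculators

For planning, closed forms replace simulation:

- **Photon budget.** The Z′ assay-quality factor for two lifetime
  populations with shared relative spread $c_v$ is
  $Z' = 1 - 3 c_v(\tau_1 + \tau_2)/|\tau_1 - \tau_2|$.  Combining with
  $c_v \approx 1/\sqrt{N_c}$ and solving for counts:
  $N_c = [\,3/(1 - Z') \cdot (1 + r)/(1 - r)\,]^2$, $r = \tau_2/\tau_1$.
  For $Z' = 0.5$ this gives 184 counts for the 10.6/4.1&nbsp;ns pair and
  100 counts at $r = 0.25$.  The exact value is reported alongside a
  nearest-integer (or ceiling) count.
- **Window duration.** A window of $\Delta t_w$ captures
  $1 - e^{-\Delta t_w/\tau}$ of emitted photons; $7\tau$ captures 99.9%.
- **Total measurement time.**
  $t_{\mathrm{tot}} = N_c \,\Delta t_w / \langle N_c\rangle_w$; with 1000
  counts, $7\tau$ windows and 0.31 counts/window/pixel this is
  $7000\,\tau/(0.31\,N_{\mathrm{Pixel}})$ — e.g. 7.5&nbsp;µs for
  $\tau = 10$ ns on 30 pixels, 0.75&nbsp;µs on 300.
- **Data rate.** If per-window pixel counts are summed to one value,
  each bin carries $\log_2(N_{\mathrm{Pixel}} + 1)$ bits and, at a bin
  width of $4\tau$,
  $d_{\mathrm{rate}} = \log_2(N_{\mathrm{Pixel}} + 1)/(4\tau)$ —
  686&nbsp;Mbit/s for 300 pixels at $\tau = 3$ ns, 0.83&nbsp;Gbit/s for
  1000.

```{r design-example}
design_report(tau_ns = 10, n_pixel = 30)
```

## Numerical choices and degenerate inputs

- Histogram bins are half-open $[k\,t_{\mathrm{res}}, (k+1)\,
  t_{\mathrm{res}})$; an event exactly at a bin edge belongs to the later
  bin, and events at $t \ge t_w$ are dropped (wrap-around into the next
  window is deliberately not modelled).
- The pile-up reduction used for histogram-only simulations operates at
  bin resolution with integer radix sorting; the earliest event per
  (window, pixel) necessarily lies in that pixel's earliest occupied bin,
  so the resulting histogram is exactly the one the event-time reduction
  produces (the tests assert byte-identity), at several times the speed.
- Near-equal exponential constants in the closed-form densities switch to
  the Gamma-limit branch to avoid catastrophic cancellation.
- Fit failures inside scans (too few populated bins at very low counts or
  very coarse bins) are excluded point-wise and reported as counts, with
  a warning — never silently interpolated.
- All randomness flows through R's session RNG; every scan-level function
  takes a `seed` and expands it into independent sub-seeds per component,
  so enlarging one component of a composite experiment does not perturb
  the others.

## Problem sizes used in the shipped studies

The packaged tests and the reproduction script run the pixel-scaling
study at `nw = 30000` with 30 replicates per grid point and 13 grid
points per pixel count — about $5\times10^8$ simulated photons, a few
minutes on one core.  Precision-law and unbiasedness checks use
100–150 replicates at 100–10,000 counts per measurement.  These sizes
were chosen so the stochastic headline quantities carry sampling errors
comfortably inside their stated tolerances while a full run stays
desk-scale.

## What the generator does and does not emulate

The simulation reproduces the *statistical* mechanism of SPAD-array
TCSPC: Poisson emission, pulse-shape convolution, uniform pixel loading,
per-pixel single-photon dead time within a window, binning, and
background.  It does not model inhomogeneous (Gaussian-profile)
illumination across the array, per-pixel dark-count heterogeneity,
afterpulsing, crosstalk, TDC nonlinearity, multi-exponential decays, or
deconvolution against a measured instrument response.  Passing tests
therefore demonstrate correctness of the counting statistics and of the
design formulas under homogeneous, single-exponential conditions — not
agreement with any particular instrument.  In real setups the effective
per-pixel maximum count rate is lower for unevenly illuminated arrays,
and absolute accuracy levels depend on the actual noise floor.
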