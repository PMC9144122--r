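# spadsim

Monte Carlo simulation and analytic design of fluorescence-lifetime
(TCSPC) measurements on SPAD array detectors.

## The problem

In time-correlated single-photon counting, a fluorophore is excited by a
short laser pulse and the arrival times of single emitted photons are
histogrammed over many measurement windows; the lifetime τ of the
single-exponential decay `I(t) = I0·exp(−t/τ)` is estimated from that
histogram by nonlinear least squares.  A single-photon avalanche diode
(SPAD) pixel registers at most one photon per window, so at high count
rates only the fastest photons are detected — the *pile-up* (first-photon)
effect — and the fitted lifetime is biased low.  Pixelated SPAD arrays
raise the tolerable count rate roughly in proportion to the number of
pixels, opening the door to microsecond-scale lifetime measurements, at
the price of a higher data rate.

`spadsim` is for detector designers and assay developers who need to
answer, before building anything: how many photons does my assay need,
how fast may I drive an N-pixel array before pile-up bites, how long does
the measurement take, and what data rate must the readout sustain?

It provides:

- a photon-level Monte Carlo of the full pipeline — Poisson emission,
  laser-pulse ⊗ decay convolution (sampled exactly as
  `U(0, fwhm) + Exp(turnoff) + Exp(τ0)`), uniform background events,
  uniform pixel loading, one-photon-per-pixel-per-window pile-up,
  binning — plus unweighted least-squares lifetime fitting with
  precision (`cv = σ/⟨τfit⟩`) and accuracy (`δτ = ⟨|τfit−τ0|/τ0⟩`)
  statistics;
- the exact first-photon detected-event density
  `μ·f(t)·exp(−(μ/N)·F(t))` as a cross-check oracle;
- pile-up scans that locate the maximum count rate `⟨Nc⟩w,max` at a
  self-calibrated accuracy threshold, and the through-origin slope of
  `⟨Nc⟩w,max` versus pixel count (≈0.31 photons/window/pixel under the
  default conditions);
- closed-form design calculators: photon budget
  `Nc = [3/(1−Z′)·(1+r)/(1−r)]²` for separating two lifetimes at
  assay quality Z′, window capture fraction `1 − exp(−Δtw/τ)`, total
  measurement time `7000·τ/(0.31·NPixel)`, and readout data rate
  `log2(NPixel+1)/(4τ)`.

## Worked example

```r
library(spadsim)

## How many photons to tell a 10.6 ns from a 4.1 ns fluorophore at Z' = 0.5?
required_counts(0.5, tau1 = 10.6, tau2 = 4.1)$nc
#> [1] 184

## Full design point: tau = 10 ns on a 30-pixel array
design_report(tau_ns = 10, n_pixel = 30)
#> <design_point> tau = 10 ns, 30 pixels
#>   photon budget (Z' = 0.5, ratio 0.25): 100 counts
#>   window: 70 ns (captures 99.9% of photons)
#>   total measurement time: 7.527 us
#>   data rate: 123.9 Mbit/s

## Simulate one measurement and fit the lifetime
set.seed(42)
m <- simulate_measurement(laser_pulse(), fluorophore(5), noise_model(0.01),
                          rate = 0.033, config = detector_config(n_pixel = 100))
m
#> <tcspc_measurement> rate 0.033/window: 1027 arrived (+322 noise), 1349 detected
#> <tcspc_histogram> 4096 bins x 0.3125 ns (window 1280 ns), 1349 counts, 0 dropped
fit_lifetime(m$histogram, skip_ns = pipeline_skip_ns(laser_pulse()))
#> <lifetime_fit> tau = 5.443 ns, I0 = 72.5 (bins 18-4096, ||r|| = 26.4)
```

The fitted lifetime fluctuates around the true 5 ns with a relative
spread set by the ~1000 detected photons (the measured coefficient of
variation at this photon count is 7–9%; see the methods vignette on the
efficiency of unweighted least squares).  The pile-up study itself:

```r
mr <- max_rate_vs_pixels(n_pixels = c(1, 3, 10, 30, 100), n_rep = 30, seed = 101)
mr
#> <max_rate_scan> threshold delta_tau = 0.065
#>  n_pixel   max_rate
#>        1  0.3391444
#>        3  0.9152578
#>       10  3.1047289
#>       30  9.2194654
#>      100 30.3430987
#>   per-pixel maximum count rate (through-origin slope): 0.304
```

Each pixel count is scanned over a log-spaced grid of count rates at
`nw = 30000` windows; the accuracy threshold is re-measured as the
pile-up-free `δτ` at 1000 photon counts; and the maximum rates fall on a
line through the origin at ≈0.31 photons per window per pixel.

A thin command-line front end mirrors the R interface
(`inst/cli/spadsim`): subcommands `simulate`, `fit`, `design`,
`scan-pileup`, `slope`, `scan-resolution`, `run-experiment`, all taking
`--config file.json`, `--seed`, `--out`.

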