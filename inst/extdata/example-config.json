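{
  "tau0_ns": 5,
  "fwhm_ns": 1.25,
  "turnoff_ns": 0.5,
  "noise_per_window": 0.01,
  "n_pixel": 100,
  "tres_ns": 0.3125,
  "tw_ns": 1280,
  "nw": 30000,
  "pileup": true,
  "rate_per_window": 0.0333,
  "n_rep": 100,
  "seed": 1
}
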