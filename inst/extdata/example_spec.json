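{
  "shape": [16, 16],
  "n_bins": 128,
  "rep_frequency": 80,
  "components": {"tau": [2.5, 4.5], "fraction": [0.4846747, 0.5153253]},
  "photons_per_pixel": 500,
  "irf": {"center": 1.5, "fwhm": 0.3},
  "noise": "poisson",
  "seed": 2024,
  "n_images": 2,
  "tau_ref": 4.0,
  "condition": "demo"
}
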