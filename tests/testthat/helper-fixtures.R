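# Shared fixture builders; everything is generated in code at test time.

# decay cube with the given counts array at 80 MHz over one full period
make_cube <- function(counts, rep_frequency = 80,
                      bin_width = (1000 / rep_frequency) / dim(counts)[3]) {
  decay_cube(counts, bin_width, rep_frequency)
}

random_cube <- function(rows, cols, bins, seed, lambda = 20,
                        rep_frequency = 80) {
  set.seed(seed)
  make_cube(array(stats::rpois(rows * cols * bins, lambda),
                  dim = c(rows, cols, bins)),
            rep_frequency = rep_frequency)
}

# phasor field built directly from coordinate matrices (white-box helper
# for exercising the lifetime formulas at chosen (g, s) points)
field_from_gs <- function(g, s, photons = NULL, omega = 0.5027,
                          calibrated = TRUE) {
  g <- as.matrix(g); s <- as.matrix(s)
  if (is.null(photons)) photons <- matrix(100, nrow(g), ncol(g))
  structure(list(g = g, s = s, photons = photons,
                 valid = matrix(TRUE, nrow(g), ncol(g)),
                 harmonic = 1L, omega = omega, calibrated = calibrated),
            class = "phasor_field")
}

# noiseless monoexponential cube + matching reference, already calibrated
calibrated_mono_field <- function(tau, tau_ref = tau, n_bins = 256,
                                  rep_frequency = 80, irf = NULL,
                                  shape = c(4, 4), photons = 1000) {
  spec <- synthetic_spec(shape = shape, n_bins = n_bins,
                         rep_frequency = rep_frequency,
                         components = data.frame(tau = tau, fraction = 1),
                         photons_per_pixel = photons, irf = irf)
  ref <- generate_reference(tau_ref, spec)
  cal <- derive_calibration(compute_phasor(ref), tau_ref)
  apply_calibration(compute_phasor(generate_cube(spec)$cube), cal)
}
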