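# flimphasor

Phasor analysis of TCSPC fluorescence lifetime imaging (FLIM) data in R.

FLIM measures how long a fluorophore stays excited before emitting a
photon; that lifetime reports on the probe's molecular environment
(quenching, binding, FRET) independently of its concentration. Raw
time-correlated single photon counting (TCSPC) data arrive as a *decay
cube*: a per-pixel histogram of photon arrival times within the laser
period. Instead of fitting exponentials pixel by pixel, phasor analysis
maps each pixel to the pair of normalised Fourier coefficients of its
decay at the laser's angular frequency ω = 2πf:

    G = Σₖ I(tₖ) cos(ω tₖ) / Σₖ I(tₖ)
    S = Σₖ I(tₖ) sin(ω tₖ) / Σₖ I(tₖ)

Monoexponential decays fall on the *universal circle* g² + s² = g;
mixtures fall inside it, on the chord between their components. From a
calibrated phasor the package computes the phase lifetime
τ_φ = tan(φ)/ω (φ = atan2(s, g)), the modulation lifetime
τ_M = √(1/M² − 1)/ω (M = √(g² + s²)) and their mean τ_avg. Calibration
against a reference dye of known monoexponential lifetime (classically
Rhodamine 6G, 4 ns in water) rotates and rescales all phasors so the
instrument response function and electronic delays cancel.

The package is aimed at microscopists comparing fluorescence lifetimes
across treatments or phenotypes — e.g. drug-induced microtubule
depolymerisation read out through the lifetime of a self-quenching
tubulin dye — and at tool builders who need a scriptable, testable FLIM
phasor backend.

## What it does

- **Read** Becker & Hickl `.sdt`, PicoQuant `.ptu` (PicoHarp-T3 records
  with line markers) and multi-page TIFF decay stacks (`read_sdt`,
  `read_ptu`, `read_tif_stack`, `read_decay`). TIFF input requires the
  time-bin width in ns — the format carries no timing metadata.
- **Transform**: per-pixel phasor at any harmonic (`compute_phasor`),
  reference calibration (`derive_calibration`, `apply_calibration`),
  lifetime maps (`lifetimes_from_phasor`), photon-count thresholds
  (`apply_photon_threshold`), FLIMfit-style sliding-window pixel binning
  (`spatial_bin`), manual masks (`read_intensity_mask`,
  `exclude_pixels`).
- **Analyse**: phasor-space ROIs mapped back to pixels
  (`phasor_roi`, `select_by_phasor_roi`), per-image / per-ROI /
  per-condition summaries (`summarize_lifetimes`), condition pooling
  (`pool_condition`), a Mann–Whitney helper on per-image means
  (`mann_whitney`; exact for ≤ 8 images per group).
- **Visualise**: phasor plots (scatter / 2-D histogram / KDE contour)
  with the universal circle, lifetime maps with ROI highlighting,
  shared-scale galleries, violin plots (`render_phasor_plot`,
  `render_lifetime_map`, `render_gallery`, `violin_data`).
- **Export**: float32 TIFF lifetime maps (masked pixels NaN), RFC-4180
  CSV summaries and per-pixel tables (`write_outputs`).
- **Simulate**: synthetic decay cubes with known ground truth — wrapped
  multiexponential decays, Gaussian IRF, Poisson noise, label patterns
  (`synthetic_spec`, `generate_cube`, `generate_reference`,
  `analytic_phasor`, `tune_mixture`) — so the whole pipeline is testable
  without instrument data.
- **Batch CLI**: `exec/flimphasor analyze|simulate|render` driven by a
  JSON config (`run_analyze`, `run_simulate`, `flim_cli`).

## Worked example

Two synthetic conditions whose ground-truth modulation lifetimes are
3.39 and 3.69 ns (two-component mixtures of 2.5 and 4.5 ns dyes, photon
fractions tuned analytically), imaged at 80 MHz with a 0.3 ns FWHM IRF,
500 photons/pixel Poisson noise, calibrated against a 4 ns reference:

```r
library(flimphasor)
omega <- angular_frequency(80)            # 0.5027 rad/ns
mix_ctrl <- tune_mixture(2.5, 4.5, 3.39, omega)
mix_noc  <- tune_mixture(2.5, 4.5, 3.69, omega)
irf <- list(center = 1.5, fwhm = 0.3)

ref <- generate_reference(4, synthetic_spec(shape = c(16, 16), n_bins = 256,
                                            photons_per_pixel = 5000, irf = irf))
cal <- derive_calibration(compute_phasor(ref), tau_ref = 4)

recs <- list(); seed <- 0
for (cond in c("ctrl", "noc")) {
  mix <- if (cond == "ctrl") mix_ctrl else mix_noc
  for (i in 1:5) {
    seed <- seed + 1
    spec <- synthetic_spec(shape = c(16, 16), n_bins = 256, components = mix,
                           photons_per_pixel = 500, irf = irf,
                           noise = "poisson", seed = seed)
    f <- apply_calibration(compute_phasor(generate_cube(spec)$cube), cal)
    maps <- lifetimes_from_phasor(f)
    recs[[length(recs) + 1]] <- summarize_lifetimes(
      maps, f, sample_id = sprintf("%s_%02d", cond, i), condition = cond)
  }
}
summary_df <- do.call(rbind, recs)
mw <- mann_whitney(summary_df$mean_tau_mod_ns[summary_df$condition == "ctrl"],
                   summary_df$mean_tau_mod_ns[summary_df$condition == "noc"])
```

Output (abridged):

```
   sample_id condition n_pixels mean_tau_phase_ns mean_tau_mod_ns
1    ctrl_01      ctrl      256             3.169           3.429
...
10    noc_05       noc      256             3.441           3.717
Mann-Whitney U = 0, two-sided p = 0.00793651 (exact (permutation enumeration))
```

Each row is one image: `mean_tau_mod_ns` is the pixel-weighted mean
modulation lifetime over valid pixels, scattered by Poisson noise around
the 3.39 / 3.69 ns ground truth. The phase lifetime sits below the
modulation lifetime because these decays are mixtures (the phasor lies
inside the universal circle). With 5 images per group and complete
separation, the exact two-sided Mann–Whitney p-value is
2/choose(10,5) = 0.0079 — the smallest attainable at this n.

## Conventions

- Images are `(row, col)` with row 1 at the top; the third array index
  is the TCSPC time bin, in time order.
- Photons are treated as arriving at bin centres `tₖ = (k − ½)·Δt`.
- ω is in rad/ns (repetition rate MHz → GHz internally); all lifetimes
  are in ns.
- Thresholds are inclusive on both ends; ROI boundaries count as inside.
- Degenerate pixels (modulation ≥ 1, phase outside `[0, π/2)`) become
  `NA` in the affected lifetime map rather than clamped values; counts
  are logged per run.

See `vignettes/phasor-analysis.Rmd` for the model, the synthetic-data
design, numerical choices and known limitations.
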