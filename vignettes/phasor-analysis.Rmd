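---
title: "Phasor analysis of TCSPC-FLIM data: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor analysis of TCSPC-FLIM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimphasor)
```

## The measurement and the model

A TCSPC-FLIM acquisition records, for every image pixel, a histogram of
photon arrival times relative to the excitation pulse: counts $I(t_k)$
in $N$ bins of width $\Delta t$ spanning (at most) one laser period
$T = 1/f$. The fluorophore's decay is convolved with the instrument
response function (IRF) and, because fluorophores with lifetimes of a
few ns do not finish decaying within a 12.5 ns period at 80 MHz,
emission from previous pulses wraps into the observed window
("incomplete decay").

Phasor analysis sidesteps decay fitting. Each pixel maps to

$$G = \frac{\sum_k I(t_k)\cos(\omega t_k)}{\sum_k I(t_k)}, \qquad
  S = \frac{\sum_k I(t_k)\sin(\omega t_k)}{\sum_k I(t_k)},$$

with $\omega = 2\pi f n$ (harmonic $n$, default 1). Key facts the
package relies on, all of them tested:

- a monoexponential of lifetime $\tau$ has continuous phasor
  $1/(1 - i\omega\tau)$, which lies on the **universal circle**
  $g^2 + s^2 = g$;
- **mixtures are linear**: a decay with photon fractions $f_i$ of
  components $P_i$ has phasor $\sum_i f_i P_i$ — inside the circle;
- **wrapping changes nothing**: the Fourier coefficients of the
  periodically wrapped decay at harmonics of $1/T$ equal those of the
  one-sided decay, so incomplete decay needs no correction;
- the IRF multiplies the phasor by its own Fourier factor, which
  **reference calibration cancels**: a measured dye of known lifetime
  $\tau_{ref}$ should sit at phase $\varphi_t = \arctan(\omega\tau_{ref})$
  and modulation $M_t = 1/\sqrt{1 + (\omega\tau_{ref})^2}$, so all
  phasors are rotated by $\varphi_t - \varphi_m$ and scaled by
  $M_t / M_m$ (photon-weighted mean over the reference's valid pixels).

From the calibrated phasor: $\tau_\varphi = \tan(\varphi)/\omega$,
$\tau_M = \sqrt{1/M^2 - 1}/\omega$, and $\tau_{avg}$ is their arithmetic
mean. For a monoexponential all three agree; for mixtures
$\tau_\varphi < \tau_M$, and the gap is a model-free heterogeneity cue.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `rep_frequency` | MHz | none (user) | sets $\omega$; must match the laser |
| `bin_width` | ns | from file metadata | TIFF has none, so it is mandatory there |
| `harmonic` | – | 1 | higher harmonics resolve short lifetimes but amplify noise |
| `tau_ref` | ns | none (user) | reference dye lifetime; 4 ns for Rhodamine 6G in water |
| `min_photons`, `max_photons` | counts | 0, ∞ | background / saturation masking; both bounds inclusive |
| `bin_radius` | px | 0 | sliding-window (2r+1)² decay summation; r = 1 is the common 3×3 bin; trades resolution for photon statistics |

Pixel binning sums *decays* before the transform, which by the pooling
identity equals photon-weighting the neighbourhood's phasors — it is not
a smoothing filter on $(g, s)$. An optional 3×3 median filter on the
$g$/$s$ maps exists (`median_filter_phasor`) but is off everywhere by
default: it distorts the photon-weighting and is not part of the
standard workflow.

## The synthetic generator: what it emulates, what it does not

`generate_cube()` realises the stated world used throughout the tests:
wrapped multiexponential decays integrated over bins (closed form per
bin; the wrap is a geometric series over pulses), optional Gaussian IRF
applied by circular convolution, expected counts scaled to a photon
budget, and per-bin Poisson draws under a mandatory seed. Label patterns
give two-population scenes for ROI tests. `analytic_phasor()` returns
the continuous-model phasor (mixture sum times the IRF's Gaussian
Fourier factor), and `tune_mixture()` solves for the photon fraction
that puts a two-component mixture at a requested $\tau_M$ — this is how
the test conditions at 3.39 and 3.69 ns are constructed from first
principles rather than by trial.

Defaults follow the conditions the method is routinely used under:
80 MHz repetition rate, 256 bins over one period, 500 photons per pixel
(a realistic budget for live-cell FLIM), reference dye at 4 ns, IRF FWHM
0.3 ns (typical for hybrid detectors). Where a scene parameter was not
externally stated we chose once and kept it.

Not modelled: detector afterpulsing and dead time, dark/background
counts, detector IRF tails (the IRF is symmetric Gaussian only),
scanning distortions, spectral bleed-through. A green test therefore
establishes correctness of the *transform, calibration and accounting*
chain under Poisson statistics — not robustness to instrument artefacts.

### Numerical details of the generator

Discrete circular convolution of two bin-integrated profiles carries a
half-bin phase lag relative to the continuous convolution
($P(a \!\ast\! b) = P(a)P(b)e^{-i\omega\Delta t/2}$). The generator
therefore convolves on a 16× oversampled grid with the IRF offset by
half a fine bin, then re-aggregates; the cube's phasor then converges to
`analytic_phasor()` at $O(N^{-2})$ (measured: ~6e-6 at 256 bins, ~4e-8
at 4096).

## Numerical and design choices

- **Bin centres.** Histogrammed photons are placed at
  $t_k = (k - \tfrac12)\Delta t$: symmetric error for binned data, and
  the convention TIFF users must match.
- **Calibration is global**, one rotation + scale per acquisition from
  the photon-weighted mean phasor of the reference. Reference images are
  uniform dye solutions, so a per-pixel transform would only add noise.
  Photon weighting (rather than unweighted pixel averaging) makes the
  estimate the maximum-use-of-data one and is our documented choice
  where the convention is ambiguous.
- **Degenerate pixels are invalidated, not clamped.** After calibration,
  noise can push a pixel to modulation $M \ge 1$ (imaginary $\tau_M$) or
  phase outside $[0, \pi/2)$ (negative $\tau_\varphi$). Clamping to 0
  would bias downstream means; the affected map gets `NA` and the counts
  are reported per run. The point $(1, 0)$ itself is the valid
  zero-lifetime pole.
- **$\tau_{avg}$** is the arithmetic mean of $\tau_\varphi$ and
  $\tau_M$. The averaging convention is not standardised across tools;
  the arithmetic mean is transparent and monotone in both inputs.
- **Summaries are pixel-weighted** (each valid pixel counts once), and
  the unit of statistical analysis is the per-image mean; per-condition
  rows are the pixel-count-weighted combination of the image rows, which
  equals the mean over the pooled cloud exactly (tested as an identity).
  Condition pooling concatenates pixels without per-image
  normalisation.
- **ROI boundaries are inclusive** (stable under floating-point jitter
  at vertices); zero-area ROIs yield an empty mask plus a warning, not
  an error.
- **Mann–Whitney helper**: exact permutation enumeration of $U$ for up
  to 8 values per group (ties handled naturally; identical groups give
  exactly $p = 1$), tie-corrected normal approximation with continuity
  correction beyond. Implemented in-package because R's `wilcox.test`
  cannot produce exact $p$ under ties; `wilcox.test` is used as an
  independent oracle on tie-free cases in the tests.
- **Multi-channel vendor files** default to channel 0; an explicit
  index selects others, and nothing is summed implicitly.
- **TIFF page order is time order**; no reversal flag, matching common
  exporter behaviour.
- **Plot conventions**: contour mode uses a Gaussian KDE with
  Scott's-rule bandwidth and levels at 25/50/75/95 % of each
  condition's peak density; the 2-D histogram defaults to 200×200 bins
  over $[0,1] \times [0,0.7]$; lifetime maps default to the 2–98 %
  percentile colour range. None of these are claimed to replicate any
  other tool's unstated conventions — they are documented defaults.
- **I/O codecs.** No TIFF/SDT/PTU reader exists in this R stack, so the
  package ships minimal, honest subsets: uncompressed grayscale baseline
  TIFF (either byte order on read), the standard SDT layout (file
  header, packed measurement description, uint16 image blocks), and PTU
  with PicoHarp-T3 records, overflow handling and line-marker image
  reconstruction (pixels assigned by sync-time fraction of their line).
  SDT stores no laser repetition rate; it can be supplied or is inferred
  from the measurement window spanning one period.

## A subtlety worth knowing: discretization vs the circle law

The universal-circle law is a property of the *continuous* transform.
With binned data, calibration cancels the discretization factor exactly
only at $\tau = \tau_{ref}$; other lifetimes keep a residual of order
$(\omega\Delta t)^2$ times the mismatch (~3e-5 in $g^2+s^2-g$ at 256
bins between 0.5 and 4 ns). This is invisible in practice — Poisson
scatter at 500 photons/pixel is two orders larger — but it is why the
property-based tests verify the circle law at fine sampling (65536
bins, residual < 1e-9) and verify separately that the 256-bin transform
converges to the analytic phasor to better than 1e-3.

## Known limitations

- Single-harmonic analysis only; no multi-harmonic joint estimation or
  phasor unmixing into component-fraction maps.
- The CLI is batch-oriented; interactive lasso selection on the phasor
  plot is out of scope (ROIs are supplied as JSON polygons/ellipses).
- Vendor formats are supported in their standard uncompressed layouts;
  compressed SDT blocks and non-PicoHarp PTU record types are rejected
  with explicit errors rather than guessed at.
- Statistics beyond the Mann–Whitney helper (ANOVA, multiple-comparison
  corrections) are deliberately left to external tools; the per-image
  CSV export is the supported interface.
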