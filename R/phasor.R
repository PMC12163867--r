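#' Per-pixel phasor transform of a decay cube
#'
#' Maps every pixel's decay histogram to phasor coordinates at harmonic `n`
#' of the laser repetition rate. With bin centres `t_k = (k - 0.5) *
#' bin_width` and angular frequency `omega = 2*pi*f*n` (rad/ns, `f` the
#' repetition rate in GHz):
#'
#' \deqn{G = \sum_k I(t_k)\cos(\omega t_k) / \sum_k I(t_k), \quad
#'       S = \sum_k I(t_k)\sin(\omega t_k) / \sum_k I(t_k)}
#'
#' Pixels with zero photons are marked invalid. The transform is invariant
#' to the intensity scale of the decay.
#'
#' @param cube a [decay_cube()].
#' @param harmonic positive integer harmonic (default 1, the fundamental).
#' @return An object of class `phasor_field`: matrices `g`, `s`, `photons`,
#'   logical `valid`, plus `harmonic`, `omega` (rad/ns) and a `calibrated`
#'   flag (FALSE until [apply_calibration()]).
#' @export
compute_phasor <- function(cube, harmonic = 1L) {
  stopifnot(inherits(cube, "decay_cube"))
  if (!is.numeric(harmonic) || length(harmonic) != 1L || harmonic < 1 ||
      harmonic != round(harmonic)) {
    stop("`harmonic` must be a positive integer", call. = FALSE)
  }
  omega <- angular_frequency(cube$rep_frequency, harmonic)
  t_k <- bin_centers(cube)
  d <- dim(cube$counts)
  flat <- matrix(cube$counts, nrow = d[1] * d[2], ncol = d[3])
  tot <- rowSums(flat)
  g <- as.vector(flat %*% cos(omega * t_k))
  s <- as.vector(flat %*% sin(omega * t_k))
  valid <- tot > 0
  g <- ifelse(valid, g / tot, NA_real_)
  s <- ifelse(valid, s / tot, NA_real_)
  structure(
    list(g = matrix(g, d[1], d[2]), s = matrix(s, d[1], d[2]),
         photons = matrix(tot, d[1], d[2]),
         valid = matrix(valid, d[1], d[2]),
         harmonic = as.integer(harmonic), omega = omega,
         calibrated = FALSE),
    class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "phasor_field: %d x %d pixels, harmonic %d (omega %.5g rad/ns), %s\n",
    nrow(x$g), ncol(x$g), x$harmonic, x$omega,
    if (isTRUE(x$calibrated)) "calibrated" else "uncalibrated"))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Derive the reference calibration transform
#'
#' Instrumental phase delay and demodulation are corrected against a
#' measurement of a dye with known monoexponential lifetime (classically
#' Rhodamine 6G, 4 ns in water). Let `(g, s)` be the photon-weighted mean
#' phasor over the reference's valid pixels, `phi_m = atan2(s, g)` and
#' `M_m = sqrt(g^2 + s^2)`. A monoexponential of lifetime `tau_ref` sits at
#' phase `phi_t = atan(omega * tau_ref)` and modulation
#' `M_t = 1 / sqrt(1 + (omega * tau_ref)^2)` on the universal circle. The
#' transform rotates by `delta_phi = phi_t - phi_m` (wrapped into
#' `(-pi, pi]`) and scales modulation by `mod_scale = M_t / M_m`.
#'
#' @param ref_field [compute_phasor()] output for the reference cube.
#' @param tau_ref known reference lifetime in ns (> 0).
#' @return An object of class `calibration_transform` with fields
#'   `delta_phi` (rad), `mod_scale`, `tau_ref`, `omega`.
#' @export
derive_calibration <- function(ref_field, tau_ref) {
  stopifnot(inherits(ref_field, "phasor_field"))
  if (!is.numeric(tau_ref) || length(tau_ref) != 1L || tau_ref <= 0) {
    stop("`tau_ref` must be a single positive lifetime in ns", call. = FALSE)
  }
  v <- ref_field$valid
  if (!any(v)) stop("reference has no valid pixels", call. = FALSE)
  w <- ref_field$photons[v]
  g_bar <- sum(w * ref_field$g[v]) / sum(w)
  s_bar <- sum(w * ref_field$s[v]) / sum(w)
  m_meas <- sqrt(g_bar^2 + s_bar^2)
  if (m_meas == 0) {
    stop("degenerate reference: measured modulation is zero", call. = FALSE)
  }
  phi_meas <- atan2(s_bar, g_bar)
  wt <- ref_field$omega * tau_ref
  phi_theo <- atan(wt)
  m_theo <- 1 / sqrt(1 + wt^2)
  delta_phi <- (phi_theo - phi_meas + pi) %% (2 * pi) - pi
  if (delta_phi == -pi) delta_phi <- pi  # wrap into (-pi, pi]
  structure(
    list(delta_phi = delta_phi, mod_scale = m_theo / m_meas,
         tau_ref = tau_ref, omega = ref_field$omega),
    class = "calibration_transform")
}

#' @export
print.calibration_transform <- function(x, ...) {
  cat(sprintf(
    "calibration_transform: rotate %.5g rad, scale modulation by %.5g\n",
    x$delta_phi, x$mod_scale))
  cat(sprintf("  reference tau %.4g ns at omega %.5g rad/ns\n",
              x$tau_ref, x$omega))
  invisible(x)
}

#' Apply a calibration transform to a phasor field
#'
#' Rotates every valid phasor by `delta_phi` and scales its modulus by
#' `mod_scale`. Fields and transforms must share the same `omega`; mixing
#' harmonics or repetition rates is an error.
#'
#' @param field a [compute_phasor()] result.
#' @param cal a [derive_calibration()] result.
#' @return the calibrated `phasor_field` (flag `calibrated = TRUE`).
#' @export
apply_calibration <- function(field, cal) {
  stopifnot(inherits(field, "phasor_field"),
            inherits(cal, "calibration_transform"))
  if (!isTRUE(all.equal(field$omega, cal$omega, tolerance = 1e-12))) {
    stop(sprintf(
      "omega mismatch: field %.9g vs calibration %.9g rad/ns",
      field$omega, cal$omega), call. = FALSE)
  }
  co <- cos(cal$delta_phi); si <- sin(cal$delta_phi)
  g2 <- cal$mod_scale * (field$g * co - field$s * si)
  s2 <- cal$mod_scale * (field$g * si + field$s * co)
  field$g <- g2
  field$s <- s2
  field$calibrated <- TRUE
  field
}

#' Lifetime maps from a calibrated phasor field
#'
#' Per-pixel phase and modulation lifetimes from the standard relations
#' `tau_phi = tan(phi) / omega` with `phi = atan2(s, g)` and
#' `tau_M = sqrt(1/M^2 - 1) / omega` with `M = sqrt(g^2 + s^2)`; the
#' average lifetime is their arithmetic mean. Degenerate pixels are not
#' clamped but invalidated: a phase outside `[0, pi/2)` (which would give a
#' negative phase lifetime) invalidates the phase (and average) lifetime,
#' `M >= 1` invalidates the modulation (and average) lifetime; counts of
#' such pixels are recorded in the `degenerate` attribute.
#'
#' @param field a calibrated `phasor_field` (a warning is raised if the
#'   field was never calibrated).
#' @return An object of class `lifetime_maps`: matrices `tau_phase`,
#'   `tau_mod`, `tau_avg` (ns, `NA` where invalid) and logical `valid`
#'   (pixels valid in all three maps).
#' @export
lifetimes_from_phasor <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  if (!isTRUE(field$calibrated)) {
    warning("computing lifetimes from an uncalibrated phasor field",
            call. = FALSE)
  }
  phi <- atan2(field$s, field$g)
  m2 <- field$g^2 + field$s^2
  ok <- field$valid & is.finite(phi) & is.finite(m2)

  # a non-negative phase lifetime needs 0 <= phi < pi/2
  phase_ok <- ok & phi > 0 & phi < pi / 2
  # zero-lifetime pole (1, 0): phi == 0 exactly is tau = 0, keep it valid
  phase_zero <- ok & phi == 0
  tau_phase <- matrix(NA_real_, nrow(field$g), ncol(field$g))
  tau_phase[phase_ok] <- tan(phi[phase_ok]) / field$omega
  tau_phase[phase_zero] <- 0
  tau_phase[phase_ok & !is.finite(tau_phase)] <- NA_real_

  mod_ok <- ok & m2 <= 1 & m2 > 0
  tau_mod <- matrix(NA_real_, nrow(field$g), ncol(field$g))
  tau_mod[mod_ok] <- sqrt(pmax(1 / m2[mod_ok] - 1, 0)) / field$omega

  tau_avg <- (tau_phase + tau_mod) / 2
  valid <- !is.na(tau_phase) & !is.na(tau_mod)
  structure(
    list(tau_phase = tau_phase, tau_mod = tau_mod, tau_avg = tau_avg,
         valid = valid),
    class = "lifetime_maps",
    degenerate = c(phase = sum(ok) - sum(phase_ok | phase_zero),
                   modulation = sum(ok) - sum(mod_ok)))
}

#' @export
print.lifetime_maps <- function(x, ...) {
  deg <- attr(x, "degenerate")
  cat(sprintf("lifetime_maps: %d x %d pixels, %d valid\n",
              nrow(x$tau_phase), ncol(x$tau_phase), sum(x$valid)))
  cat(sprintf("  degenerate: %d phase, %d modulation\n",
              deg[["phase"]], deg[["modulation"]]))
  if (any(x$valid)) {
    cat(sprintf("  mean tau (ns): phase %.4g, mod %.4g, avg %.4g\n",
                mean(x$tau_phase[x$valid]), mean(x$tau_mod[x$valid]),
                mean(x$tau_avg[x$valid])))
  }
  invisible(x)
}

#' Photon-count threshold mask
#'
#' Background masking by photon budget: a pixel is kept iff its total
#' photon count lies in `[min_photons, max_photons]` (both bounds
#' inclusive; `max_photons = NULL` means no upper bound).
#'
#' @param cube a [decay_cube()].
#' @param min_photons lower bound (>= 0).
#' @param max_photons upper bound or `NULL`.
#' @return logical matrix, `TRUE` for kept pixels.
#' @export
apply_photon_threshold <- function(cube, min_photons = 0,
                                   max_photons = NULL) {
  stopifnot(inherits(cube, "decay_cube"))
  if (min_photons < 0) stop("`min_photons` must be >= 0", call. = FALSE)
  if (!is.null(max_photons) && max_photons <= min_photons) {
    stop("`max_photons` must exceed `min_photons`", call. = FALSE)
  }
  tot <- photon_counts(cube)
  mask <- tot >= min_photons
  if (!is.null(max_photons)) mask <- mask & tot <= max_photons
  mask
}

#' Sliding-window spatial binning of a decay cube
#'
#' Replaces each pixel's decay by the sum of the decays in its
#' `(2 * bin_radius + 1)^2` square neighbourhood, truncated at the image
#' edges. The spatial shape is preserved (no downsampling), trading spatial
#' resolution for photon statistics as in FLIMfit-style binning: radius 1
#' is the common "3x3 bin".
#'
#' @param cube a [decay_cube()].
#' @param bin_radius non-negative integer radius; 0 returns the cube as is.
#' @return a [decay_cube()] of the same shape with summed counts.
#' @export
spatial_bin <- function(cube, bin_radius = 0L) {
  stopifnot(inherits(cube, "decay_cube"))
  if (bin_radius < 0 || bin_radius != round(bin_radius)) {
    stop("`bin_radius` must be a non-negative integer", call. = FALSE)
  }
  if (bin_radius == 0) return(cube)
  d <- dim(cube$counts)
  r <- bin_radius
  out <- array(0, dim = d)
  # cumulative sums over rows/cols as triangular matrix products, so the
  # code is safe for single-row or single-column images
  low <- matrix(as.numeric(row(diag(d[1])) >= col(diag(d[1]))), d[1], d[1])
  upp <- matrix(as.numeric(row(diag(d[2])) <= col(diag(d[2]))), d[2], d[2])
  for (b in seq_len(d[3])) {
    # summed-area table with one row/col of zero padding
    sat <- matrix(0, d[1] + 1L, d[2] + 1L)
    sat[-1, -1] <- low %*% matrix(cube$counts[, , b], d[1], d[2]) %*% upp
    i0 <- pmax(seq_len(d[1]) - r - 1L, 0L)
    i1 <- pmin(seq_len(d[1]) + r, d[1])
    j0 <- pmax(seq_len(d[2]) - r - 1L, 0L)
    j1 <- pmin(seq_len(d[2]) + r, d[2])
    out[, , b] <- sat[i1 + 1L, j1 + 1L, drop = FALSE] -
      sat[i0 + 1L, j1 + 1L, drop = FALSE] -
      sat[i1 + 1L, j0 + 1L, drop = FALSE] +
      sat[i0 + 1L, j0 + 1L, drop = FALSE]
  }
  decay_cube(out, cube$bin_width, cube$rep_frequency,
             source_path = cube$source_path, channel = cube$channel)
}

#' Optional median smoothing of phasor coordinate maps
#'
#' Applies `passes` rounds of a 3x3 median filter to the `g` and `s` maps
#' (edges use the in-bounds neighbourhood). Off by default in every
#' pipeline; provided for very low-photon data where the per-pixel phasor
#' scatter obscures structure.
#'
#' @param field a `phasor_field`.
#' @param passes number of filter passes (0 = no-op).
#' @return the filtered `phasor_field`.
#' @export
median_filter_phasor <- function(field, passes = 1L) {
  stopifnot(inherits(field, "phasor_field"), passes >= 0)
  med3 <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    out <- m
    for (i in seq_len(n1)) {
      for (j in seq_len(n2)) {
        nb <- m[max(1, i - 1):min(n1, i + 1), max(1, j - 1):min(n2, j + 1)]
        out[i, j] <- stats::median(nb, na.rm = TRUE)
      }
    }
    out
  }
  for (p in seq_len(passes)) {
    field$g <- med3(field$g)
    field$s <- med3(field$s)
  }
  field
}
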