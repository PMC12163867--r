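test_that("compute_phasor matches the direct summation oracle", {
  cube <- random_cube(8, 8, 64, seed = 11)
  field <- compute_phasor(cube)
  omega <- angular_frequency(80)
  t_k <- (seq_len(64) - 0.5) * cube$bin_width
  for (i in 1:8) {
    for (j in 1:8) {
      dec <- cube$counts[i, j, ]
      expect_equal(field$g[i, j], sum(dec * cos(omega * t_k)) / sum(dec),
                   tolerance = 1e-12)
      expect_equal(field$s[i, j], sum(dec * sin(omega * t_k)) / sum(dec),
                   tolerance = 1e-12)
    }
  }
  expect_equal(field$photons, rowSums(cube$counts, dims = 2))
})

test_that("phasor of canonical decays is the closed form", {
  # all photons in the first bin: a delta at t0 = bin_width / 2
  counts <- array(0, dim = c(1, 1, 32))
  counts[1, 1, 1] <- 500
  cube <- make_cube(counts)
  f <- compute_phasor(cube)
  omega <- angular_frequency(80)
  t0 <- cube$bin_width / 2
  expect_equal(f$g[1, 1], cos(omega * t0), tolerance = 1e-12)
  expect_equal(f$s[1, 1], sin(omega * t0), tolerance = 1e-12)

  # uniform decay over exactly one period: cos/sin orthogonality -> (0, 0)
  cube_u <- make_cube(array(7, dim = c(2, 2, 64)))
  f_u <- compute_phasor(cube_u)
  expect_lt(max(abs(f_u$g)), 1e-12)
  expect_lt(max(abs(f_u$s)), 1e-12)
})

test_that("zero-photon pixels are invalid and harmonics are checked", {
  counts <- array(1, dim = c(2, 2, 16))
  counts[2, 1, ] <- 0
  f <- compute_phasor(make_cube(counts))
  expect_false(f$valid[2, 1])
  expect_true(is.na(f$g[2, 1]))
  expect_true(all(f$valid[-2]))
  expect_error(compute_phasor(make_cube(counts), harmonic = 0),
               "positive integer")
  f2 <- compute_phasor(make_cube(counts), harmonic = 2)
  expect_equal(f2$omega, 2 * angular_frequency(80), tolerance = 1e-12)
})

test_that("phasor is invariant to the intensity scale", {
  cube <- random_cube(3, 3, 32, seed = 5)
  f1 <- compute_phasor(cube)
  f2 <- compute_phasor(make_cube(cube$counts * 17))
  expect_equal(f1$g, f2$g, tolerance = 1e-12)
  expect_equal(f1$s, f2$s, tolerance = 1e-12)
})

test_that("derive_calibration recovers constructed transforms", {
  omega <- angular_frequency(80)
  tau_ref <- 4
  wt <- omega * tau_ref
  phi_t <- atan(wt)
  m_t <- 1 / sqrt(1 + wt^2)
  # spec numbers: omega * tau = 2.0106 at 80 MHz / 4 ns
  expect_equal(wt, 2 * pi * 0.08 * 4, tolerance = 1e-12)

  # reference already at the theoretical position: identity transform
  f_id <- field_from_gs(m_t * cos(phi_t), m_t * sin(phi_t), omega = omega,
                        calibrated = FALSE)
  cal <- derive_calibration(f_id, tau_ref)
  expect_equal(cal$delta_phi, 0, tolerance = 1e-12)
  expect_equal(cal$mod_scale, 1, tolerance = 1e-12)

  # reference rotated by +0.3 rad and scaled by 0.7: inverse transform
  rot <- 0.3
  g_m <- 0.7 * m_t * cos(phi_t + rot)
  s_m <- 0.7 * m_t * sin(phi_t + rot)
  cal2 <- derive_calibration(field_from_gs(g_m, s_m, omega = omega,
                                           calibrated = FALSE), tau_ref)
  expect_equal(cal2$delta_phi, -0.3, tolerance = 1e-12)
  expect_equal(cal2$mod_scale, 1 / 0.7, tolerance = 1e-12)
})

test_that("calibration uses the photon-weighted mean and fails cleanly", {
  omega <- angular_frequency(80)
  g <- matrix(c(0.2, 0.6), 1, 2)
  s <- matrix(c(0.2, 0.3), 1, 2)
  w <- matrix(c(100, 300), 1, 2)
  f <- field_from_gs(g, s, photons = w, omega = omega, calibrated = FALSE)
  cal <- derive_calibration(f, 4)
  g_bar <- sum(w * g) / sum(w); s_bar <- sum(w * s) / sum(w)
  wt <- omega * 4
  expect_equal(cal$delta_phi, atan(wt) - atan2(s_bar, g_bar),
               tolerance = 1e-12)
  expect_equal(cal$mod_scale,
               (1 / sqrt(1 + wt^2)) / sqrt(g_bar^2 + s_bar^2),
               tolerance = 1e-12)

  f_none <- f; f_none$valid[] <- FALSE
  expect_error(derive_calibration(f_none, 4), "no valid pixels")
  f_zero <- field_from_gs(matrix(0), matrix(0), omega = omega)
  expect_error(derive_calibration(f_zero, 4), "degenerate")
  expect_error(derive_calibration(f, -1), "positive")
})

test_that("apply_calibration composes and guards omega", {
  cube <- random_cube(4, 4, 64, seed = 7)
  f <- compute_phasor(cube)
  id <- structure(list(delta_phi = 0, mod_scale = 1, tau_ref = 4,
                       omega = f$omega), class = "calibration_transform")
  f_id <- apply_calibration(f, id)
  expect_equal(f_id$g, f$g, tolerance = 1e-15)
  expect_true(f_id$calibrated)

  cal <- structure(list(delta_phi = 0.41, mod_scale = 1.3, tau_ref = 4,
                        omega = f$omega), class = "calibration_transform")
  inv <- structure(list(delta_phi = -0.41, mod_scale = 1 / 1.3, tau_ref = 4,
                        omega = f$omega), class = "calibration_transform")
  back <- apply_calibration(apply_calibration(f, cal), inv)
  expect_equal(back$g, f$g, tolerance = 1e-12)
  expect_equal(back$s, f$s, tolerance = 1e-12)

  cal_bad <- structure(list(delta_phi = 0, mod_scale = 1, tau_ref = 4,
                            omega = f$omega * 2),
                       class = "calibration_transform")
  expect_error(apply_calibration(f, cal_bad), "omega mismatch")
})

test_that("lifetime formulas and degenerate handling are correct", {
  omega <- 0.5027
  f <- field_from_gs(cbind(1, 0.5, 0.4, -0.2, 0.7),
                     cbind(0, 0.5, 0.3, 0.3, 0.8), omega = omega)
  maps <- lifetimes_from_phasor(f)
  # (1, 0): zero-lifetime pole
  expect_equal(maps$tau_phase[1, 1], 0)
  expect_equal(maps$tau_mod[1, 1], 0)
  # (0.5, 0.5): on the universal circle, both lifetimes 1/omega
  expect_equal(maps$tau_phase[1, 2], 1 / omega, tolerance = 1e-12)
  expect_equal(maps$tau_mod[1, 2], 1 / omega, tolerance = 1e-12)
  # random interior point: direct formulas
  expect_equal(maps$tau_phase[1, 3], tan(atan2(0.3, 0.4)) / omega,
               tolerance = 1e-12)
  expect_equal(maps$tau_mod[1, 3], sqrt(1 / 0.25 - 1) / omega,
               tolerance = 1e-12)
  expect_equal(maps$tau_avg[1, 3],
               (maps$tau_phase[1, 3] + maps$tau_mod[1, 3]) / 2,
               tolerance = 1e-12)
  # phi outside [0, pi/2): negative tan, invalid phase lifetime, not clamped
  expect_true(is.na(maps$tau_phase[1, 4]))
  f_neg <- field_from_gs(0.4, -0.1, omega = omega)
  expect_true(is.na(lifetimes_from_phasor(f_neg)$tau_phase[1, 1]))
  # M > 1: invalid modulation lifetime
  expect_true(is.na(maps$tau_mod[1, 5]))
  expect_false(maps$valid[1, 4])
  deg <- attr(maps, "degenerate")
  expect_equal(unname(deg["phase"]), 1)
  expect_equal(unname(deg["modulation"]), 1)
  expect_warning(lifetimes_from_phasor(
    field_from_gs(0.5, 0.3, calibrated = FALSE)), "uncalibrated")
})

# The circle law is a property of the continuous transform: calibration
# cancels bin discretization exactly only at tau = tau_ref, leaving a
# residual O((omega*dt)^2 * |tau - tau_ref|) elsewhere. The tests therefore
# run at fine time sampling (65536 bins), where that residual sits below
# the 1e-9 tolerance; convergence at practical 256-bin sampling is covered
# by the analytic-phasor convergence test (test-synthetic.R).
test_that("universal-circle law holds for calibrated monoexponentials", {
  for (tau in c(0.5, 1, 2, 3.39, 3.69, 4)) {
    f <- calibrated_mono_field(tau, tau_ref = 4, shape = c(1, 1),
                               n_bins = 65536)
    expect_lt(max(abs(f$g^2 + f$s^2 - f$g)), 1e-9)
    maps <- lifetimes_from_phasor(f)
    expect_lt(abs(mean(maps$tau_phase) - tau), 1e-6)
    expect_lt(abs(mean(maps$tau_mod) - tau), 1e-6)
  }
})

test_that("shared-IRF calibration lands samples on the universal circle", {
  irf <- list(center = 1.5, fwhm = 0.4)
  f <- calibrated_mono_field(2.2, tau_ref = 4, irf = irf, shape = c(1, 1),
                             n_bins = 65536)
  expect_lt(max(abs(f$g^2 + f$s^2 - f$g)), 1e-9)
})

test_that("mixtures are linear in the pure-component phasors", {
  omega <- angular_frequency(80)
  p1 <- analytic_phasor(1.2, omega)
  p2 <- analytic_phasor(3.8, omega)
  for (fr in c(0, 0.25, 0.5, 0.75, 1)) {
    comp <- data.frame(tau = c(1.2, 3.8), fraction = c(fr, 1 - fr))
    spec <- synthetic_spec(shape = c(1, 1), n_bins = 2048,
                           components = comp, photons_per_pixel = 1e4)
    f <- compute_phasor(generate_cube(spec)$cube)
    expect_equal(f$g[1, 1], fr * p1["g"] + (1 - fr) * p2["g"],
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(f$s[1, 1], fr * p1["s"] + (1 - fr) * p2["s"],
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("recovered lifetime is monotone in true lifetime", {
  taus <- seq(0.2, 3, length.out = 12)  # within (0, period / 4)
  rec <- vapply(taus, function(tau) {
    f <- calibrated_mono_field(tau, tau_ref = 4, shape = c(1, 1),
                               n_bins = 256)
    lifetimes_from_phasor(f)$tau_mod[1, 1]
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("photon thresholds are inclusive and validated", {
  counts <- array(0, dim = c(3, 3, 4))
  tot <- matrix(1:9, 3, 3)
  for (b in 1:4) counts[, , b] <- tot / 4  # non-integer per bin is fine
  counts <- array(0, dim = c(3, 3, 4))
  counts[, , 1] <- tot
  cube <- make_cube(counts)
  expect_true(all(apply_photon_threshold(cube, 0, NULL)))
  m <- apply_photon_threshold(cube, 3, 7)
  expect_equal(sum(m), 5)
  expect_equal(unname(m), unname(tot >= 3 & tot <= 7))
  m_max <- apply_photon_threshold(cube, 9, NULL)
  expect_equal(which(m_max), which(tot == 9))
  expect_error(apply_photon_threshold(cube, 5, 5), "exceed")
  expect_error(apply_photon_threshold(cube, -1), ">= 0")
})

test_that("spatial binning is a sliding-window sum with edge truncation", {
  cube <- random_cube(5, 6, 8, seed = 9)
  expect_identical(spatial_bin(cube, 0), cube)
  b1 <- spatial_bin(cube, 1)
  # brute-force neighbourhood oracle
  for (i in c(1, 3, 5)) {
    for (j in c(1, 4, 6)) {
      ii <- max(1, i - 1):min(5, i + 1)
      jj <- max(1, j - 1):min(6, j + 1)
      expect_equal(b1$counts[i, j, ],
                   apply(cube$counts[ii, jj, , drop = FALSE], 3, sum),
                   tolerance = 1e-12)
    }
  }
  # centre of a 3x3 image with radius 1: sum of all decays
  c3 <- random_cube(3, 3, 8, seed = 10)
  expect_equal(spatial_bin(c3, 1)$counts[2, 2, ],
               apply(c3$counts, 3, sum), tolerance = 1e-12)
  expect_error(spatial_bin(cube, -1), "non-negative")
})

test_that("binned phasor equals the photon-weighted mean phasor (pooling)", {
  cube <- random_cube(3, 3, 32, seed = 12)
  f <- compute_phasor(cube)
  fb <- compute_phasor(spatial_bin(cube, 1))
  w <- f$photons
  expect_equal(fb$g[2, 2], sum(w * f$g) / sum(w), tolerance = 1e-12)
  expect_equal(fb$s[2, 2], sum(w * f$s) / sum(w), tolerance = 1e-12)
})

test_that("decay_cube validates input and warns on long windows", {
  expect_error(decay_cube(array(-1, dim = c(1, 1, 2)), 0.1, 80),
               "non-negative")
  expect_error(decay_cube(array(1, dim = c(1, 1, 2)), -0.1, 80), "positive")
  expect_warning(decay_cube(array(1, dim = c(1, 1, 64)), 0.5, 80),
                 "exceeds the laser period")
  # exactly one period plus less than one bin: no warning
  expect_silent(decay_cube(array(1, dim = c(1, 1, 64)), 12.5 / 64, 80))
})
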