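#' Specification of a synthetic TCSPC acquisition
#'
#' Describes a simulated FLIM acquisition with known ground truth: image
#' shape, TCSPC timing, the mixture of exponential decay components, the
#' expected photon budget per pixel, an optional Gaussian instrument
#' response function (IRF) and the noise model. Decays are modelled as
#' periodic ("wrapped") exponentials: at typical 80 MHz repetition rates a
#' 3-4 ns fluorophore has not fully decayed within one 12.5 ns period, so
#' emission from earlier pulses folds into the observed histogram. The
#' generator models this exactly via the geometric series over periods.
#'
#' @param shape integer vector `c(rows, cols)`.
#' @param n_bins number of TCSPC time bins.
#' @param bin_width ns per bin; defaults to one laser period / `n_bins`.
#' @param rep_frequency laser repetition rate in MHz.
#' @param components data.frame with columns `tau` (ns, > 0) and `fraction`
#'   (photon fractions summing to 1).
#' @param photons_per_pixel expected photon count per pixel (> 0).
#' @param irf `NULL` for an ideal delta IRF, or `list(center =, fwhm =)`
#'   in ns for a Gaussian IRF applied by circular convolution.
#' @param noise `"none"` or `"poisson"` (per-bin Poisson draws).
#' @param seed integer RNG seed; mandatory when `noise = "poisson"`.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(32L, 32L), n_bins = 256L,
                           bin_width = NULL, rep_frequency = 80,
                           components = data.frame(tau = 4, fraction = 1),
                           photons_per_pixel = 500,
                           irf = NULL, noise = c("none", "poisson"),
                           seed = NULL) {
  noise <- match.arg(noise)
  if (is.null(bin_width)) bin_width <- (1000 / rep_frequency) / n_bins
  stopifnot(length(shape) == 2L, all(shape >= 1), n_bins >= 2,
            bin_width > 0, rep_frequency > 0, photons_per_pixel > 0)
  components <- as.data.frame(components)
  if (!all(c("tau", "fraction") %in% names(components))) {
    stop("`components` needs columns `tau` and `fraction`", call. = FALSE)
  }
  if (any(components$tau <= 0)) stop("all `tau` must be > 0", call. = FALSE)
  if (abs(sum(components$fraction) - 1) > 1e-9) {
    stop("component fractions must sum to 1", call. = FALSE)
  }
  period <- 1000 / rep_frequency
  if (any(components$tau >= 50 * period)) {
    warning("a lifetime is >= 50x the laser period; its decay is ",
            "indistinguishable from a constant", call. = FALSE)
  }
  if (!is.null(irf)) {
    stopifnot(is.list(irf), all(c("center", "fwhm") %in% names(irf)),
              irf$fwhm > 0)
  }
  if (noise == "poisson" && is.null(seed)) {
    stop("`seed` is mandatory when noise = \"poisson\"", call. = FALSE)
  }
  structure(
    list(shape = as.integer(shape), n_bins = as.integer(n_bins),
         bin_width = bin_width, rep_frequency = rep_frequency,
         components = components, photons_per_pixel = photons_per_pixel,
         irf = irf, noise = noise, seed = seed),
    class = "synthetic_spec")
}

# Per-bin integral of a wrapped monoexponential, normalised to unit sum.
# For decay exp(-t/tau) wrapped over period T = N * dt, the integral over
# bin k is proportional to exp(-k*dt/tau); the wrap contributes only the
# constant factor 1/(1 - exp(-T/tau)) which normalisation removes.
wrapped_exp_profile <- function(tau, n_bins, bin_width) {
  k <- 0:(n_bins - 1)
  p <- exp(-k * bin_width / tau)
  p / sum(p)
}

# Gaussian IRF integrated over wrapped bins (sum over +-6 sigma of periods),
# normalised to unit sum.
gaussian_irf_profile <- function(center, fwhm, n_bins, bin_width) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  period <- n_bins * bin_width
  edges <- (0:n_bins) * bin_width
  n_wrap <- ceiling((6 * sigma + abs(center)) / period) + 1L
  p <- numeric(n_bins)
  for (w in -n_wrap:n_wrap) {
    cdf <- stats::pnorm(edges + w * period, mean = center, sd = sigma)
    p <- p + diff(cdf)
  }
  p / sum(p)
}

circular_convolve <- function(a, b) {
  n <- length(a)
  Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / n
}

#' Expected per-bin counts of one pixel's decay
#'
#' Evaluates the noiseless generative model: a photon-fraction mixture of
#' wrapped (periodic) exponentials, bin-integrated, optionally circularly
#' convolved with the Gaussian IRF, scaled to `photons_per_pixel`.
#'
#' @param spec a [synthetic_spec()].
#' @return numeric vector of `n_bins` expected counts.
#' @export
generate_decay <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  # With an IRF the convolution runs on a 16x oversampled time grid and the
  # IRF is offset by half a fine bin: discrete circular convolution of two
  # bin-integrated profiles carries a half-bin phase lag relative to the
  # continuous model (P(a conv b) = P(a) P(b) exp(-i omega dt / 2)), and the
  # shift cancels it, so the cube's phasor converges to analytic_phasor().
  m <- if (is.null(spec$irf)) 1L else 16L
  nf <- spec$n_bins * m
  bwf <- spec$bin_width / m
  prof <- numeric(nf)
  for (i in seq_len(nrow(spec$components))) {
    prof <- prof + spec$components$fraction[i] *
      wrapped_exp_profile(spec$components$tau[i], nf, bwf)
  }
  if (!is.null(spec$irf)) {
    irf <- gaussian_irf_profile(spec$irf$center + bwf / 2, spec$irf$fwhm,
                                nf, bwf)
    prof <- circular_convolve(prof, irf)
    prof[prof < 0] <- 0  # fft round-off
    # aggregate fine bins back to acquisition bins (sums of integrals)
    prof <- colSums(matrix(prof, nrow = m))
    prof <- prof / sum(prof)
  }
  prof * spec$photons_per_pixel
}

#' Analytic phasor of a decay model
#'
#' Closed-form phasor of the continuous generative model at angular
#' frequency `omega`: the photon-fraction-weighted sum of the
#' monoexponential phasors `1 / (1 - i * omega * tau)` (whose real and
#' imaginary parts are `1/(1 + (omega*tau)^2)` and
#' `omega*tau/(1 + (omega*tau)^2)`), multiplied by the Fourier factor of
#' the Gaussian IRF, `exp(i*omega*center - omega^2*sigma^2/2)`, when one is
#' present. Wrapping over the laser period does not change the continuous
#' phasor at harmonics of the repetition rate. The discrete phasor of a
#' binned cube converges to this value as the bin count grows.
#'
#' @param components data.frame with `tau` (ns) and `fraction` columns, or
#'   a single lifetime in ns.
#' @param omega angular frequency in rad/ns.
#' @param irf `NULL` or `list(center =, fwhm =)` in ns.
#' @return named numeric vector `c(g =, s =)`.
#' @export
analytic_phasor <- function(components, omega, irf = NULL) {
  if (is.numeric(components)) {
    components <- data.frame(tau = components,
                             fraction = rep(1 / length(components),
                                            length(components)))
  }
  wt <- omega * components$tau
  p <- sum(components$fraction * (1 + 1i * wt) / (1 + wt^2))
  if (!is.null(irf)) {
    sigma <- irf$fwhm / (2 * sqrt(2 * log(2)))
    p <- p * exp(1i * omega * irf$center - omega^2 * sigma^2 / 2)
  }
  c(g = Re(p), s = Im(p))
}

#' Lifetimes a perfect analysis would recover for a decay model
#'
#' Phase and modulation lifetimes of the IRF-free analytic phasor; for a
#' monoexponential both equal `tau`, for mixtures the phase lifetime is
#' below and the modulation lifetime above the intensity-weighted mean.
#'
#' @inheritParams analytic_phasor
#' @return named vector `c(tau_phase =, tau_mod =, tau_avg =)` in ns.
#' @export
analytic_lifetimes <- function(components, omega) {
  p <- analytic_phasor(components, omega)
  phi <- atan2(p["s"], p["g"])
  m <- sqrt(sum(p^2))
  tp <- unname(tan(phi) / omega)
  tm <- unname(sqrt(1 / m^2 - 1) / omega)
  c(tau_phase = tp, tau_mod = tm, tau_avg = (tp + tm) / 2)
}

#' Tune a two-component mixture to a target modulation lifetime
#'
#' Finds the photon fraction `f` of the first component such that the
#' mixture `f * tau1 + (1 - f) * tau2` has the requested modulation
#' lifetime at `omega`. Used to build synthetic conditions whose ground
#' truth matches a stated modulation lifetime.
#'
#' @param tau1,tau2 component lifetimes in ns (`tau1 < target < tau2`).
#' @param target_tau_mod desired modulation lifetime in ns.
#' @param omega angular frequency in rad/ns.
#' @return components data.frame usable in [synthetic_spec()].
#' @export
tune_mixture <- function(tau1, tau2, target_tau_mod, omega) {
  stopifnot(min(tau1, tau2) < target_tau_mod,
            max(tau1, tau2) > target_tau_mod)
  f <- stats::uniroot(function(f) {
    comp <- data.frame(tau = c(tau1, tau2), fraction = c(f, 1 - f))
    analytic_lifetimes(comp, omega)[["tau_mod"]] - target_tau_mod
  }, interval = c(0, 1), tol = 1e-12)$root
  data.frame(tau = c(tau1, tau2), fraction = c(f, 1 - f))
}

#' Generate a synthetic decay cube with ground truth
#'
#' Builds a full decay cube from a [synthetic_spec()]. With a label
#' `pattern` (integer matrix matching `spec$shape`) each pixel draws its
#' decay model from `components_by_label`, enabling two-population scenes
#' such as filaments over background; without one the image is uniform.
#' Poisson noise, when requested, is applied independently per bin with
#' the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param pattern optional integer label matrix (`spec$shape`).
#' @param components_by_label named list mapping label (as character) to a
#'   components data.frame; required when `pattern` is given.
#' @return list with elements `cube` (a [decay_cube()]), `truth` (list of
#'   `tau_phase`, `tau_mod`, `tau_avg` matrices from the analytic IRF-free
#'   model) and `spec`.
#' @export
generate_cube <- function(spec, pattern = NULL, components_by_label = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- spec$shape[1]; cols <- spec$shape[2]
  omega <- angular_frequency(spec$rep_frequency)
  if (is.null(pattern)) {
    pattern <- matrix(1L, rows, cols)
    components_by_label <- list("1" = spec$components)
  } else {
    if (!all(dim(pattern) == spec$shape)) {
      stop("`pattern` shape does not match spec$shape", call. = FALSE)
    }
    labs <- as.character(sort(unique(as.vector(pattern))))
    missing_labs <- setdiff(labs, names(components_by_label))
    if (length(missing_labs)) {
      stop("unknown pattern label(s): ", paste(missing_labs, collapse = ", "),
           call. = FALSE)
    }
  }
  counts <- array(0, dim = c(rows, cols, spec$n_bins))
  tau_phase <- matrix(NA_real_, rows, cols)
  tau_mod <- matrix(NA_real_, rows, cols)
  for (lab in unique(as.vector(pattern))) {
    sp <- spec
    sp$components <- components_by_label[[as.character(lab)]]
    expected <- generate_decay(sp)
    sel <- which(pattern == lab)
    for (b in seq_len(spec$n_bins)) {
      slice <- counts[, , b]
      slice[sel] <- expected[b]
      counts[, , b] <- slice
    }
    lt <- analytic_lifetimes(sp$components, omega)
    tau_phase[sel] <- lt[["tau_phase"]]
    tau_mod[sel] <- lt[["tau_mod"]]
  }
  if (spec$noise == "poisson") {
    set.seed(spec$seed)
    counts <- array(stats::rpois(length(counts), lambda = counts),
                    dim = dim(counts))
  }
  cube <- decay_cube(counts, spec$bin_width, spec$rep_frequency,
                     source_path = "<synthetic>")
  list(cube = cube,
       truth = list(tau_phase = tau_phase, tau_mod = tau_mod,
                    tau_avg = (tau_phase + tau_mod) / 2),
       spec = spec)
}

#' Generate a monoexponential reference cube
#'
#' A spatially uniform cube of a single-lifetime dye (e.g. Rhodamine 6G,
#' 4 ns in water) sharing the sample acquisition's timing and IRF, suitable
#' for [derive_calibration()].
#'
#' @param tau_ref reference lifetime in ns.
#' @param spec a [synthetic_spec()] supplying shape, timing, IRF, photon
#'   budget and noise; its `components` are replaced by the reference dye.
#' @return a [decay_cube()].
#' @export
generate_reference <- function(tau_ref, spec) {
  stopifnot(tau_ref > 0)
  sp <- spec
  sp$components <- data.frame(tau = tau_ref, fraction = 1)
  generate_cube(sp)$cube
}

#' Write a synthetic dataset to disk
#'
#' Materialises a generated cube as a multi-page TIFF decay stack plus
#' float32 TIFF ground-truth lifetime maps and a JSON sidecar recording the
#' spec, so any downstream tool can be exercised without real acquisitions.
#'
#' @param gen result of [generate_cube()].
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return (invisibly) named list of written paths.
#' @export
write_synthetic_dataset <- function(gen, dir, name = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    stack = file.path(dir, paste0(name, ".tif")),
    tau_phase = file.path(dir, paste0(name, "_true_tau_phase.tif")),
    tau_mod = file.path(dir, paste0(name, "_true_tau_mod.tif")),
    spec = file.path(dir, paste0(name, "_spec.json")))
  # TIFF interchange stores integer photon counts; noiseless expected
  # counts are rounded on export (the in-memory cube keeps full precision)
  write_tiff(round(gen$cube$counts), paths$stack, format = "uint")
  write_tiff(gen$truth$tau_phase, paths$tau_phase, format = "float")
  write_tiff(gen$truth$tau_mod, paths$tau_mod, format = "float")
  sp <- gen$spec
  sidecar <- list(shape = sp$shape, n_bins = sp$n_bins,
                  bin_width = sp$bin_width, rep_frequency = sp$rep_frequency,
                  components = sp$components,
                  photons_per_pixel = sp$photons_per_pixel,
                  irf = sp$irf, noise = sp$noise, seed = sp$seed)
  jsonlite::write_json(sidecar, paths$spec, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
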