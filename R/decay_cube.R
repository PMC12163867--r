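#' TCSPC decay cube
#'
#' A decay cube holds the per-pixel photon-arrival-time histograms of one
#' FLIM acquisition: a `rows x cols x n_bins` array of non-negative photon
#' counts together with the acquisition timing (time-bin width in ns and
#' laser repetition rate in MHz). The spatial convention is `(row, col)`
#' with row 1 at the top of the displayed image; the third index is the
#' TCSPC time bin, in time order.
#'
#' @param counts numeric array `rows x cols x n_bins` (a `rows x cols`
#'   matrix is accepted for a single time bin) of non-negative integer
#'   photon counts. Stored as doubles so pooled totals cannot overflow.
#' @param bin_width width of one time bin in ns; must be positive.
#' @param rep_frequency laser repetition rate in MHz; must be positive.
#' @param source_path optional provenance string (file the cube came from).
#' @param channel integer channel index the cube was read from (0-based).
#'
#' @details A warning (not an error) is raised when the measurement window
#'   `n_bins * bin_width` exceeds one laser period by more than one bin
#'   width: such files are usually mis-specified but still analysable.
#'
#' @return An object of class `decay_cube` with fields `counts`,
#'   `bin_width`, `rep_frequency`, `n_bins`, `source_path`, `channel`.
#' @export
decay_cube <- function(counts, bin_width, rep_frequency,
                       source_path = NA_character_, channel = 0L) {
  if (is.matrix(counts)) {
    counts <- array(counts, dim = c(dim(counts), 1L))
  }
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    stop("`counts` must be a rows x cols x bins array", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0)) {
    stop("photon counts must be non-negative and non-missing", call. = FALSE)
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("`bin_width` must be a single positive number (ns)", call. = FALSE)
  }
  if (!is.numeric(rep_frequency) || length(rep_frequency) != 1L ||
      rep_frequency <= 0) {
    stop("`rep_frequency` must be a single positive number (MHz)",
         call. = FALSE)
  }
  n_bins <- dim(counts)[3L]
  period <- 1000 / rep_frequency  # ns
  if (n_bins * bin_width > period + bin_width) {
    warning(sprintf(
      "measurement window (%.4g ns) exceeds the laser period (%.4g ns)",
      n_bins * bin_width, period), call. = FALSE)
  }
  structure(
    list(counts = counts, bin_width = bin_width,
         rep_frequency = rep_frequency, n_bins = n_bins,
         source_path = source_path, channel = as.integer(channel)),
    class = "decay_cube")
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "decay_cube: %d x %d pixels, %d bins of %.5g ns (window %.4g ns), %g MHz\n",
    d[1], d[2], x$n_bins, x$bin_width, x$n_bins * x$bin_width,
    x$rep_frequency))
  cat(sprintf("  total photons: %.6g  source: %s (channel %d)\n",
              sum(x$counts), x$source_path, x$channel))
  invisible(x)
}

#' @export
dim.decay_cube <- function(x) dim(x$counts)

#' Per-pixel photon totals of a decay cube
#'
#' @param cube a [decay_cube()].
#' @return numeric matrix `rows x cols` of summed counts.
#' @export
photon_counts <- function(cube) {
  stopifnot(inherits(cube, "decay_cube"))
  rowSums(cube$counts, dims = 2L)
}

#' Angular frequency of the phasor transform
#'
#' Converts a repetition rate in MHz and a harmonic number into the angular
#' frequency `omega = 2 * pi * f_GHz * harmonic` in rad/ns used throughout.
#'
#' @param rep_frequency laser repetition rate in MHz.
#' @param harmonic positive integer harmonic (1 = fundamental).
#' @return angular frequency in rad/ns.
#' @export
angular_frequency <- function(rep_frequency, harmonic = 1L) {
  if (harmonic < 1 || harmonic != round(harmonic)) {
    stop("`harmonic` must be a positive integer", call. = FALSE)
  }
  2 * pi * rep_frequency * 1e-3 * harmonic
}

#' Time-bin centres of a decay cube
#'
#' Bin k (1-based) is centred at `(k - 0.5) * bin_width` ns; histogrammed
#' photons are treated as arriving at the centre of their bin.
#'
#' @param cube a [decay_cube()].
#' @return numeric vector of length `n_bins`, in ns.
#' @export
bin_centers <- function(cube) {
  (seq_len(cube$n_bins) - 0.5) * cube$bin_width
}
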