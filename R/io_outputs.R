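# Result export: float32 TIFF lifetime maps (masked pixels NaN) and
# RFC-4180 CSV summary tables with a fixed header.

.summary_columns <- c("sample_id", "condition", "scope", "n_pixels",
                      "n_photons", "mean_tau_phase_ns", "mean_tau_mod_ns",
                      "mean_tau_avg_ns")

#' Write lifetime maps and summary tables
#'
#' Lifetime maps go out as 32-bit float single-page TIFFs (one per map,
#' invalid/masked pixels stored as NaN); summary records as a CSV with
#' header `sample_id, condition, scope, n_pixels, n_photons,
#' mean_tau_phase_ns, mean_tau_mod_ns, mean_tau_avg_ns`. Optionally a
#' per-pixel CSV (`row, col, g, s, photons, tau_phase_ns, tau_mod_ns,
#' tau_avg_ns`) is written so external statistics can start from raw pixel
#' values.
#'
#' @param maps a [lifetimes_from_phasor()] result, or `NULL` to skip maps.
#' @param summaries data.frame of summary records ([summarize_lifetimes()]
#'   rows), or `NULL`.
#' @param out_dir output directory, created if absent.
#' @param prefix filename prefix for the map TIFFs.
#' @param mask optional logical matrix; pixels outside it become NaN.
#' @param per_pixel optional list with `field` (a `phasor_field`) to export
#'   the per-pixel table alongside.
#' @return (invisibly) named character vector of written paths.
#' @export
write_outputs <- function(maps = NULL, summaries = NULL, out_dir,
                          prefix = "sample", mask = NULL,
                          per_pixel = NULL) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory: %s", out_dir),
         call. = FALSE)
  }
  written <- character(0)
  if (!is.null(maps)) {
    for (which in c("tau_phase", "tau_mod", "tau_avg")) {
      m <- maps[[which]]
      if (!is.null(mask)) m[!mask] <- NA_real_
      m[is.na(m)] <- NaN
      p <- file.path(out_dir, sprintf("%s_%s.tif", prefix, which))
      write_tiff(m, p, format = "float")
      written[which] <- p
    }
  }
  if (!is.null(summaries)) {
    p <- file.path(out_dir, "summary.csv")
    df <- as.data.frame(summaries)[, .summary_columns, drop = FALSE]
    utils::write.csv(df, p, row.names = FALSE, na = "")
    written["summary"] <- p
  }
  if (!is.null(per_pixel)) {
    fl <- per_pixel$field
    sel <- if (is.null(per_pixel$mask)) fl$valid else fl$valid & per_pixel$mask
    idx <- which(sel, arr.ind = TRUE)
    df <- data.frame(row = idx[, 1], col = idx[, 2],
                     g = fl$g[sel], s = fl$s[sel],
                     photons = fl$photons[sel])
    if (!is.null(per_pixel$maps)) {
      df$tau_phase_ns <- per_pixel$maps$tau_phase[sel]
      df$tau_mod_ns <- per_pixel$maps$tau_mod[sel]
      df$tau_avg_ns <- per_pixel$maps$tau_avg[sel]
    }
    p <- file.path(out_dir, sprintf("%s_pixels.csv", prefix))
    utils::write.csv(df, p, row.names = FALSE, na = "")
    written["per_pixel"] <- p
  }
  invisible(written)
}

#' Read a sample-to-condition assignment table
#'
#' Two-column CSV (`file_path, condition`; an optional leading `sample_id`
#' column is honoured, otherwise sample ids are the file basenames without
#' extension). Sample ids must be unique and every file must exist.
#'
#' @param path CSV path.
#' @param check_files verify that each `file_path` exists (default TRUE).
#' @return data.frame with columns `sample_id`, `file_path`, `condition`.
#' @export
read_condition_table <- function(path, check_files = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        strip.white = TRUE)
  if (!all(c("file_path", "condition") %in% names(df))) {
    stop("condition table needs columns `file_path` and `condition`",
         call. = FALSE)
  }
  if (is.null(df$sample_id)) {
    df$sample_id <- tools::file_path_sans_ext(basename(df$file_path))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in condition table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (check_files) {
    missing <- df$file_path[!file.exists(df$file_path)]
    if (length(missing)) {
      stop("condition table references missing file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  df[, c("sample_id", "file_path", "condition")]
}

#' Read any supported decay-cube format by extension
#'
#' Dispatches on the file extension: `.sdt`, `.ptu` or `.tif`/`.tiff`.
#'
#' @param path input file.
#' @param channel 0-based channel for vendor formats.
#' @param bin_width ns per bin (required for TIFF input).
#' @param rep_frequency MHz (required for TIFF, optional override for SDT).
#' @return a [decay_cube()].
#' @export
read_decay <- function(path, channel = 0L, bin_width = NULL,
                       rep_frequency = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    sdt = read_sdt(path, channel = channel, rep_frequency = rep_frequency),
    ptu = read_ptu(path, channel = channel),
    tif = ,
    tiff = read_tif_stack(path, bin_width = bin_width,
                          rep_frequency = rep_frequency),
    stop(sprintf("unsupported decay-cube format: .%s (%s)", ext, path),
         call. = FALSE))
}
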