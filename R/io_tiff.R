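# Minimal baseline TIFF codec: single-sample (grayscale) images, no
# compression, little-endian writer, endian-aware reader. Decay stacks are
# multi-page TIFFs with one page per time bin; lifetime maps are float32
# single-page TIFFs with NaN at masked pixels. No TIFF library ships with
# this R stack, so the subset needed here is implemented directly.

.tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)

# ---- writer ---------------------------------------------------------------

#' Write a grayscale TIFF (single- or multi-page)
#'
#' Writes an uncompressed little-endian baseline TIFF, one page per slice of
#' the third array dimension. `format = "uint"` stores counts as 16- or
#' 32-bit unsigned integers (chosen from the data range); `format = "float"`
#' stores 32-bit IEEE floats and preserves `NA`/`NaN` as NaN.
#'
#' @param data numeric matrix (`rows x cols`) or array (`rows x cols x
#'   pages`), row 1 = top of image.
#' @param path output file path.
#' @param format `"uint"` or `"float"`.
#' @return (invisibly) the path.
#' @export
write_tiff <- function(data, path, format = c("uint", "float")) {
  format <- match.arg(format)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (format == "uint") {
    if (anyNA(data) || any(data < 0) || any(data != round(data))) {
      stop("uint TIFF requires non-negative integral values", call. = FALSE)
    }
    bits <- if (max(data) <= 65535) 16L else 32L
    if (max(data) > 2^31 - 1) {
      stop("counts exceed the 32-bit unsigned TIFF writer range",
           call. = FALSE)
    }
    sample_format <- 1L
  } else {
    bits <- 32L
    sample_format <- 3L
  }
  bytes_pp <- bits / 8L
  page_bytes <- d[1] * d[2] * bytes_pp
  n <- d[3]
  ifd_entries <- 10L
  ifd_size <- 2L + ifd_entries * 12L + 4L
  data_start <- 8L
  ifd_start <- data_start + n * page_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  for (p in seq_len(n)) {
    vals <- as.vector(t(data[, , p]))  # TIFF strips are row-major
    if (format == "float") {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else {
      suppressWarnings(
        writeBin(as.integer(vals), con, size = bytes_pp, endian = "little"))
    }
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  for (p in seq_len(n)) {
    writeBin(ifd_entries, con, size = 2, endian = "little")
    entry(256, .tiff_types["LONG"], 1, d[2])                 # ImageWidth
    entry(257, .tiff_types["LONG"], 1, d[1])                 # ImageLength
    entry(258, .tiff_types["SHORT"], 1, bits)                # BitsPerSample
    entry(259, .tiff_types["SHORT"], 1, 1)                   # Compression
    entry(262, .tiff_types["SHORT"], 1, 1)                   # BlackIsZero
    entry(273, .tiff_types["LONG"], 1,
          data_start + (p - 1L) * page_bytes)                # StripOffsets
    entry(277, .tiff_types["SHORT"], 1, 1)                   # SamplesPerPixel
    entry(278, .tiff_types["LONG"], 1, d[1])                 # RowsPerStrip
    entry(279, .tiff_types["LONG"], 1, page_bytes)           # StripByteCounts
    entry(339, .tiff_types["SHORT"], 1, sample_format)       # SampleFormat
    next_ifd <- if (p < n) ifd_start + p * ifd_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

# ---- reader ---------------------------------------------------------------

read_uint <- function(raw, offset, size, endian) {
  v <- readBin(raw[(offset + 1):(offset + size)], "integer", n = 1L,
               size = size, endian = endian,
               signed = size >= 4L)
  if (size == 4L && v < 0) v <- v + 2^32
  as.numeric(v)
}

read_uint_vec <- function(raw, offset, size, n, endian) {
  v <- readBin(raw[(offset + 1):(offset + n * size)], "integer", n = n,
               size = size, endian = endian, signed = size >= 4L)
  v <- as.numeric(v)
  if (size == 4L) v[v < 0] <- v[v < 0] + 2^32
  v
}

tiff_format_error <- function(path, why) {
  stop(sprintf("not a readable TIFF: %s (%s)", path, why), call. = FALSE)
}

# Parse the IFD chain; returns a list of page descriptors.
tiff_ifds <- function(raw, path) {
  if (length(raw) < 8) tiff_format_error(path, "file too short")
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   tiff_format_error(path, "bad byte-order mark"))
  if (read_uint(raw, 2, 2, endian) != 42) {
    tiff_format_error(path, "bad magic number")
  }
  ifd_offset <- read_uint(raw, 4, 4, endian)
  pages <- list()
  while (ifd_offset != 0) {
    if (ifd_offset + 2 > length(raw)) tiff_format_error(path, "bad IFD offset")
    n_entries <- read_uint(raw, ifd_offset, 2, endian)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_offset + 2 + (e - 1) * 12
      tag <- read_uint(raw, base, 2, endian)
      type <- read_uint(raw, base + 2, 2, endian)
      count <- read_uint(raw, base + 4, 4, endian)
      # BYTE/SHORT/LONG carry all layout tags we use; skip other types
      tsize <- if (type >= 1 && type <= 5) c(1, NA, 2, 4, NA)[type] else NA
      if (is.na(tsize)) next
      if (count * tsize <= 4) {
        vals <- read_uint_vec(raw, base + 8, tsize, count, endian)
      } else {
        off <- read_uint(raw, base + 8, 4, endian)
        vals <- read_uint_vec(raw, off, tsize, count, endian)
      }
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_offset <- read_uint(raw, ifd_offset + 2 + n_entries * 12, 4, endian)
  }
  attr(pages, "endian") <- endian
  pages
}

tiff_tag <- function(tags, tag, default = NULL) {
  v <- tags[[as.character(tag)]]
  if (is.null(v)) default else v
}

decode_tiff_page <- function(raw, tags, endian, path) {
  width <- tiff_tag(tags, 256); height <- tiff_tag(tags, 257)
  if (is.null(width) || is.null(height)) {
    tiff_format_error(path, "page missing dimensions")
  }
  bits <- tiff_tag(tags, 258, 1)[1]
  if (tiff_tag(tags, 259, 1) != 1) {
    tiff_format_error(path, "compressed TIFF not supported")
  }
  if (tiff_tag(tags, 277, 1) != 1) {
    tiff_format_error(path, "only single-sample (grayscale) TIFF supported")
  }
  fmt <- tiff_tag(tags, 339, 1)[1]
  offsets <- tiff_tag(tags, 273)
  counts <- tiff_tag(tags, 279)
  if (is.null(offsets) || is.null(counts)) {
    tiff_format_error(path, "page missing strip layout")
  }
  buf <- raw(0)
  for (i in seq_along(offsets)) {
    buf <- c(buf, raw[(offsets[i] + 1):(offsets[i] + counts[i])])
  }
  size <- bits / 8
  n_px <- width * height
  vals <- if (fmt == 3) {
    readBin(buf, "double", n = n_px, size = size, endian = endian)
  } else if (fmt == 2) {
    readBin(buf, "integer", n = n_px, size = size, endian = endian,
            signed = TRUE)
  } else {
    v <- readBin(buf, "integer", n = n_px, size = size, endian = endian,
                 signed = size >= 4)
    v <- as.numeric(v)
    if (size == 4) v[v < 0] <- v[v < 0] + 2^32
    v
  }
  matrix(as.numeric(vals), nrow = height, ncol = width, byrow = TRUE)
}

#' Read a grayscale TIFF into an array
#'
#' Reads an uncompressed single-sample TIFF (any byte order; 8/16/32-bit
#' unsigned or signed integers, or 32/64-bit floats) as a
#' `rows x cols x pages` array.
#'
#' @param path TIFF file path.
#' @return numeric array `rows x cols x pages`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pages <- tiff_ifds(raw, path)
  if (!length(pages)) tiff_format_error(path, "no pages")
  endian <- attr(pages, "endian")
  mats <- lapply(pages, function(tg) decode_tiff_page(raw, tg, endian, path))
  shp <- vapply(mats, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    tiff_format_error(path, sprintf(
      "pages of unequal shape (%s)",
      paste(unique(apply(shp, 2, paste, collapse = "x")), collapse = " vs ")))
  }
  out <- array(0, dim = c(shp[1, 1], shp[2, 1], length(mats)))
  for (p in seq_along(mats)) out[, , p] <- mats[[p]]
  out
}

#' Read a multi-page TIFF decay stack
#'
#' One TIFF page per TCSPC time bin, pages in time order. TIFF files carry
#' no timing metadata, so the time-bin width (ns) must be supplied by the
#' caller; the laser repetition rate is likewise required to place the
#' phasor frequency.
#'
#' @param path multi-page TIFF path.
#' @param bin_width ns per time bin (required for .tif input).
#' @param rep_frequency laser repetition rate in MHz.
#' @return a [decay_cube()].
#' @export
read_tif_stack <- function(path, bin_width = NULL, rep_frequency = NULL) {
  if (is.null(bin_width)) {
    stop("bin width (ns) is required for .tif input: this format has no ",
         "timing metadata", call. = FALSE)
  }
  if (is.null(rep_frequency)) {
    stop("`rep_frequency` (MHz) is required for .tif input", call. = FALSE)
  }
  arr <- read_tiff(path)
  if (any(arr != round(arr)) || any(arr < 0)) {
    stop(sprintf("decay stack %s has non-integral or negative counts", path),
         call. = FALSE)
  }
  decay_cube(arr, bin_width, rep_frequency, source_path = path)
}

#' Read a binary intensity mask image
#'
#' Nonzero pixels are included, zero pixels excluded. The mask image must
#' match the decay cube's spatial shape exactly.
#'
#' @param path grayscale TIFF path.
#' @param shape integer vector `c(rows, cols)` of the target cube.
#' @return logical matrix, `TRUE` = included.
#' @export
read_intensity_mask <- function(path, shape) {
  arr <- read_tiff(path)
  m <- arr[, , 1]
  if (dim(arr)[3] > 1) {
    warning("mask has multiple pages; using the first", call. = FALSE)
  }
  if (!all(dim(m) == shape)) {
    stop(sprintf("mask shape %dx%d does not match image shape %dx%d",
                 nrow(m), ncol(m), shape[1], shape[2]), call. = FALSE)
  }
  m != 0
}
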