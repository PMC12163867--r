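# Becker & Hickl .sdt container, standard-layout subset: the 42-byte file
# header, one measurement-description block (packed MEASURE_INFO struct,
# little-endian) and uncompressed uint16 image data blocks (one per
# detector channel), pixel-major with the ADC time bins contiguous per
# pixel. The byte offsets below follow the published MEASURE_INFO layout:
#   tac_r  float32 @ 64   TAC range, seconds
#   tac_g  int16   @ 68   TAC gain
#   adc_re int16   @ 82   ADC resolution (time bins)
#   scan_x int32   @ 173  image width  (pixels)
#   scan_y int32   @ 177  image height (pixels)
# bin width = tac_r / tac_g / adc_re; the measurement window is
# tac_r / tac_g.

.sdt_header_valid <- 0x5555
.sdt_block_header_bytes <- 22L
.sdt_meas_desc_bytes <- 211L

sdt_format_error <- function(path, why) {
  stop(sprintf("not a readable SDT file: %s (%s)", path, why), call. = FALSE)
}

#' Read a Becker & Hickl .sdt decay cube
#'
#' Parses the standard SDT layout (uncompressed uint16 image data blocks);
#' each data block is treated as one detector channel. The time axis comes
#' from the TAC range/gain and ADC resolution in the measurement
#' description. SDT files do not store the laser repetition rate; supply it
#' in MHz, or leave `NULL` to assume the measurement window spans exactly
#' one laser period.
#'
#' @param path .sdt file path.
#' @param channel 0-based data-block (channel) index.
#' @param rep_frequency laser repetition rate in MHz, or `NULL` to infer
#'   from the measurement window.
#' @return a [decay_cube()].
#' @export
read_sdt <- function(path, channel = 0L, rep_frequency = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 42) sdt_format_error(path, "file too short")
  hdr <- function(off, size, what = "integer", signed = TRUE) {
    readBin(raw[(off + 1):(off + size)], what, n = 1L, size = size,
            endian = "little", signed = signed)
  }
  header_valid <- hdr(32, 2, signed = FALSE)
  if (header_valid != .sdt_header_valid) {
    sdt_format_error(path, "header-valid flag not set")
  }
  meas_offs <- hdr(24, 4)
  n_blocks <- hdr(18, 2)
  block_offs <- hdr(14, 4)
  if (meas_offs <= 0 || meas_offs + 189 > length(raw)) {
    sdt_format_error(path, "bad measurement-description offset")
  }
  mi <- function(off, size, what = "integer", signed = TRUE) {
    hdr(meas_offs + off, size, what, signed)
  }
  tac_r <- mi(64, 4, "double")
  tac_g <- mi(68, 2)
  adc_re <- mi(82, 2)
  scan_x <- mi(173, 4)
  scan_y <- mi(177, 4)
  if (adc_re <= 0 || tac_r <= 0 || tac_g <= 0) {
    sdt_format_error(path, "invalid TAC/ADC timing fields")
  }
  if (scan_x <= 0 || scan_y <= 0) {
    sdt_format_error(path, "invalid scan dimensions")
  }
  if (channel < 0 || channel >= n_blocks) {
    stop(sprintf(
      "channel %d not present in %s; available channels: %s",
      channel, path, paste(seq_len(n_blocks) - 1L, collapse = ", ")),
      call. = FALSE)
  }
  # walk the data-block chain to the requested channel
  off <- block_offs
  for (b in seq_len(channel + 1L)) {
    if (off + .sdt_block_header_bytes > length(raw)) {
      sdt_format_error(path, "truncated data-block chain")
    }
    data_offs <- hdr(off + 2, 4)
    next_offs <- hdr(off + 6, 4)
    block_type <- hdr(off + 10, 2, signed = FALSE)
    block_length <- hdr(off + 18, 4)
    if (b <= channel) off <- next_offs
  }
  if (bitwAnd(block_type, 0x2000) != 0) {
    sdt_format_error(path, "compressed data blocks not supported")
  }
  n_expect <- scan_x * scan_y * adc_re
  if (block_length < 2 * n_expect) {
    sdt_format_error(path, sprintf(
      "data block holds %d bytes, expected %d", block_length, 2 * n_expect))
  }
  if (data_offs + 2 * n_expect > length(raw)) {
    sdt_format_error(path, "data block extends past end of file")
  }
  v <- readBin(raw[(data_offs + 1):(data_offs + 2 * n_expect)], "integer",
               n = n_expect, size = 2, endian = "little", signed = FALSE)
  # stored order: time bins fastest, then columns, then rows
  counts <- aperm(array(as.numeric(v), dim = c(adc_re, scan_x, scan_y)),
                  c(3, 2, 1))
  bin_width_ns <- tac_r / tac_g / adc_re * 1e9
  if (is.null(rep_frequency)) {
    rep_frequency <- 1000 / (tac_r / tac_g * 1e9)
  }
  decay_cube(counts, bin_width_ns, rep_frequency,
             source_path = path, channel = channel)
}

#' Write a minimal Becker & Hickl .sdt fixture
#'
#' Emits the same standard layout [read_sdt()] parses: file header,
#' measurement description (TAC range/gain, ADC resolution, scan size) and
#' one uncompressed uint16 data block per channel. Intended for generating
#' reader test fixtures and small interchange files, not for feature-
#' complete SDT authoring.
#'
#' @param channels list of `rows x cols x n_bins` count arrays (one per
#'   channel), or a single array.
#' @param path output path.
#' @param window_ns measurement window (TAC range / gain) in ns.
#' @return (invisibly) the path.
#' @export
write_sdt <- function(channels, path, window_ns) {
  if (is.array(channels) && !is.list(channels)) channels <- list(channels)
  d <- dim(channels[[1]])
  stopifnot(length(d) == 3L, window_ns > 0)
  for (ch in channels) {
    stopifnot(identical(dim(ch), d), all(ch >= 0), all(ch == round(ch)),
              max(ch) <= 65535)
  }
  n_bins <- d[3]
  tac_g <- 1L
  tac_r <- window_ns * 1e-9
  info <- charToRaw(paste(
    "*IDENTIFICATION",
    "  ID        : SPC Setup & Data File",
    "  Title     : synthetic fixture",
    "*END",
    "", sep = "\r\n"))
  header_len <- 42L
  info_offs <- header_len
  meas_offs <- info_offs + length(info)
  block_offs <- meas_offs + .sdt_meas_desc_bytes
  block_bytes <- 2L * prod(d)

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  # file header (42 bytes)
  w16(0x0295)                      # revision
  w32(info_offs); w16(length(info))
  w32(0L); w16(0L)                 # setup block: none
  w32(block_offs); w16(length(channels))
  w32(.sdt_block_header_bytes + block_bytes)
  w32(meas_offs); w16(1L); w16(.sdt_meas_desc_bytes)
  w16(.sdt_header_valid)
  w32(0L); w16(0L)                 # reserved
  w16(0L)                          # checksum (not verified by readers)
  writeBin(info, con)
  # measurement description: zero-filled packed struct with the timing and
  # scan fields populated at their standard offsets
  mi <- raw(.sdt_meas_desc_bytes)
  poke <- function(off, bytes) {
    mi[(off + 1):(off + length(bytes))] <<- bytes
  }
  le <- function(x, size, float = FALSE) {
    if (float) writeBin(as.numeric(x), raw(), size = size, endian = "little")
    else writeBin(as.integer(x), raw(), size = size, endian = "little")
  }
  poke(0, c(charToRaw("00:00:00"), as.raw(0)))    # time a9
  poke(9, c(charToRaw("2000-01-01"), as.raw(0)))  # date a11
  poke(64, le(tac_r, 4, float = TRUE))
  poke(68, le(tac_g, 2))
  poke(82, le(n_bins, 2))
  poke(173, le(d[2], 4))                      # scan_x = cols
  poke(177, le(d[1], 4))                      # scan_y = rows
  writeBin(mi, con)
  # data blocks
  off <- block_offs
  for (i in seq_along(channels)) {
    data_offs <- off + .sdt_block_header_bytes
    next_offs <- data_offs + block_bytes
    w16(i - 1L)            # block_no
    w32(data_offs)
    w32(if (i < length(channels)) next_offs else 0L)
    w16(0x0001)            # block_type: measured data, uncompressed
    w16(0L)                # meas_desc_block_no
    w32(i - 1L)            # lblock_no
    w32(block_bytes)
    # time bins fastest, then columns, then rows
    v <- as.integer(aperm(channels[[i]], c(3, 2, 1)))
    suppressWarnings(writeBin(v, con, size = 2, endian = "little"))
    off <- next_offs
  }
  invisible(path)
}
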