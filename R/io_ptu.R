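# PicoQuant .ptu container with PicoHarp-T3 TTTR records. The header is a
# sequence of 48-byte tagged entries (32-byte ident, int32 index, uint32
# type, 8-byte value); records are uint32 with nsync in bits 0-15, the TCSPC
# time bin (dtime) in bits 16-27 and the channel in bits 28-31. Channel 15
# marks special records: dtime 0 is a sync-counter overflow (+65536), any
# other dtime carries marker bits. Images are scanned line by line between
# LineStart/LineStop markers; pixels are assigned by their sync-time
# fraction of the line.

.ptu_magic <- "PQTTTR"
.ptu_ty_int8 <- 0x10000008
.ptu_ty_float8 <- 0x20000008
.ptu_ty_empty8 <- 0xFFFF0008
.ptu_ty_ansistring <- 0x4001FFFF
.ptu_rectype_pht3 <- 0x00010303
.ptu_wrap <- 65536

ptu_format_error <- function(path, why) {
  stop(sprintf("not a readable PTU file: %s (%s)", path, why), call. = FALSE)
}

# ---- reader ---------------------------------------------------------------

ptu_read_header <- function(raw, path) {
  if (length(raw) < 16 ||
      rawToChar(raw[1:6]) != .ptu_magic) {
    ptu_format_error(path, "missing PQTTTR magic")
  }
  pos <- 16L  # 8-byte magic + 8-byte version
  tags <- list()
  repeat {
    if (pos + 48 > length(raw)) ptu_format_error(path, "truncated header")
    ident_raw <- raw[(pos + 1):(pos + 32)]
    ident <- rawToChar(ident_raw[ident_raw != as.raw(0)])
    typ <- readBin(raw[(pos + 37):(pos + 40)], "integer", size = 4,
                   endian = "little")
    if (typ < 0) typ <- typ + 2^32
    val_raw <- raw[(pos + 41):(pos + 48)]
    pos <- pos + 48L
    if (typ == .ptu_ty_float8) {
      value <- readBin(val_raw, "double", size = 8, endian = "little")
    } else {
      lo <- readBin(val_raw[1:4], "integer", size = 4, endian = "little")
      hi <- readBin(val_raw[5:8], "integer", size = 4, endian = "little")
      if (lo < 0) lo <- lo + 2^32
      value <- lo + hi * 2^32
      if (typ == .ptu_ty_ansistring) {
        # value is the byte length of the string that follows
        pos <- pos + as.integer(value)
        value <- NA
      }
    }
    if (ident == "Header_End") break
    tags[[ident]] <- value
  }
  list(tags = tags, data_start = pos)
}

ptu_require_tag <- function(tags, name, path) {
  if (is.null(tags[[name]])) {
    ptu_format_error(path, sprintf("required header tag %s is absent", name))
  }
  tags[[name]]
}

#' Read a PicoQuant .ptu image into a decay cube
#'
#' Supports PicoHarp-T3 TTTR records with line-scan image markers. Photon
#' records are binned into a per-pixel histogram: rows advance at each
#' LineStart marker (reset by Frame markers), columns by the photon's
#' sync-time fraction of its line, and the TCSPC bin is the record's dtime.
#' Bin width and repetition rate come from the `MeasDesc_Resolution` and
#' `MeasDesc_GlobalResolution` header tags.
#'
#' @param path .ptu file path.
#' @param channel 0-based detector channel (record channel minus one).
#' @return a [decay_cube()].
#' @export
read_ptu <- function(path, channel = 0L) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  hd <- ptu_read_header(raw, path)
  tags <- hd$tags
  rectype <- ptu_require_tag(tags, "TTResultFormat_TTTRRecType", path)
  if (rectype != .ptu_rectype_pht3) {
    ptu_format_error(path, sprintf(
      "unsupported TTTR record type 0x%08x (only PicoHarp T3)", rectype))
  }
  res_s <- ptu_require_tag(tags, "MeasDesc_Resolution", path)
  glob_s <- ptu_require_tag(tags, "MeasDesc_GlobalResolution", path)
  pix_x <- ptu_require_tag(tags, "ImgHdr_PixX", path)
  pix_y <- ptu_require_tag(tags, "ImgHdr_PixY", path)
  m_start <- ptu_require_tag(tags, "ImgHdr_LineStart", path)
  m_stop <- ptu_require_tag(tags, "ImgHdr_LineStop", path)
  m_frame <- tags[["ImgHdr_Frame"]]  # optional: single frame if absent

  n_rec <- (length(raw) - hd$data_start) %/% 4L
  v <- readBin(raw[(hd$data_start + 1):(hd$data_start + 4L * n_rec)],
               "integer", n = n_rec, size = 4, endian = "little")
  v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32
  chan <- v %/% 2^28
  dtime <- (v %/% 2^16) %% 4096
  nsync <- v %% 2^16
  special <- chan == 15
  is_ofl <- special & dtime == 0
  t_sync <- nsync + .ptu_wrap * (cumsum(is_ofl) - is_ofl)

  marker_bit <- function(m) special & !is_ofl & (dtime %/% 2^(m - 1)) %% 2 == 1
  t_line_start <- t_sync[marker_bit(m_start)]
  t_line_stop <- t_sync[marker_bit(m_stop)]
  if (!length(t_line_start) || length(t_line_stop) < length(t_line_start)) {
    ptu_format_error(path, "incomplete line marker stream")
  }
  t_frame <- if (is.null(m_frame)) numeric(0) else t_sync[marker_bit(m_frame)]
  # row index of each line: position within its frame
  frame_of_line <- findInterval(t_line_start, t_frame)
  row_of_line <- stats::ave(seq_along(t_line_start), frame_of_line,
                            FUN = seq_along)

  photon <- !special & dtime < 4096
  available <- sort(unique(chan[photon])) - 1
  keep <- photon & chan == channel + 1
  if (!any(keep)) {
    if (length(available)) {
      stop(sprintf(
        "channel %d has no photons in %s; available channels: %s",
        channel, path, paste(available, collapse = ", ")), call. = FALSE)
    }
  }
  n_bins <- max(1L, as.integer(round(glob_s / res_s)))
  n_bins <- min(n_bins, 4096L)
  counts <- array(0, dim = c(pix_y, pix_x, n_bins))
  if (any(keep)) {
    tp <- t_sync[keep]
    dt <- dtime[keep]
    line <- findInterval(tp, t_line_start)
    ok <- line >= 1 & tp < t_line_stop[pmin(line, length(t_line_stop))] &
      dt < n_bins
    line <- line[ok]; tp <- tp[ok]; dt <- dt[ok]
    col <- pmin(floor(pix_x * (tp - t_line_start[line]) /
                        (t_line_stop[line] - t_line_start[line])),
                pix_x - 1)
    row <- row_of_line[line]
    inb <- row <= pix_y
    idx <- cbind(row[inb], col[inb] + 1, dt[inb] + 1)
    for (i in seq_len(nrow(idx))) {
      counts[idx[i, 1], idx[i, 2], idx[i, 3]] <-
        counts[idx[i, 1], idx[i, 2], idx[i, 3]] + 1
    }
  }
  decay_cube(counts, bin_width = res_s * 1e9,
             rep_frequency = 1e-6 / glob_s,
             source_path = path, channel = channel)
}

# ---- writer ---------------------------------------------------------------

ptu_tag_raw <- function(ident, typ, value) {
  ident_raw <- c(charToRaw(ident), raw(32 - nchar(ident)))
  idx <- writeBin(-1L, raw(), size = 4, endian = "little")
  typ_raw <- writeBin(as.integer(
    if (typ > 2^31 - 1) typ - 2^32 else typ), raw(), size = 4,
    endian = "little")
  val_raw <- if (typ == .ptu_ty_float8) {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else {
    lo <- value %% 2^32
    hi <- value %/% 2^32
    c(writeBin(as.integer(if (lo > 2^31 - 1) lo - 2^32 else lo), raw(),
               size = 4, endian = "little"),
      writeBin(as.integer(hi), raw(), size = 4, endian = "little"))
  }
  c(ident_raw, idx, typ_raw, val_raw)
}

ptu_record <- function(chan, dtime, nsync) {
  chan * 2^28 + dtime * 2^16 + nsync
}

#' Write a minimal PicoQuant .ptu fixture
#'
#' Encodes count arrays as PicoHarp-T3 TTTR streams with Frame and
#' LineStart/LineStop markers in the same layout [read_ptu()] parses: each
#' photon of time-bin `b` in pixel `(row, col)` becomes one T3 record whose
#' dtime is `b - 1` and whose sync time sits at the centre of that pixel's
#' share of its line. Intended for reader fixtures, not general authoring.
#'
#' @param channels list of `rows x cols x n_bins` arrays (detector channels
#'   1, 2, ...), or a single array.
#' @param path output path.
#' @param bin_width ns per TCSPC bin (`MeasDesc_Resolution`).
#' @param rep_frequency laser repetition rate in MHz
#'   (`MeasDesc_GlobalResolution` is its reciprocal).
#' @param syncs_per_pixel laser periods spent on each pixel.
#' @return (invisibly) the path.
#' @export
write_ptu <- function(channels, path, bin_width, rep_frequency,
                      syncs_per_pixel = 8L) {
  if (is.array(channels) && !is.list(channels)) channels <- list(channels)
  d <- dim(channels[[1]])
  stopifnot(length(d) == 3L, bin_width > 0, rep_frequency > 0,
            syncs_per_pixel >= 1)
  for (ch in channels) {
    stopifnot(identical(dim(ch), d), all(ch >= 0), all(ch == round(ch)))
  }
  if (d[3] > 4096) stop("PicoHarp T3 dtime is 12-bit: at most 4096 bins",
                        call. = FALSE)
  rows <- d[1]; cols <- d[2]; spp <- syncs_per_pixel

  # event list in chronological sync order
  ev_chan <- numeric(0); ev_dtime <- numeric(0); ev_t <- numeric(0)
  add <- function(chan, dtime, t) {
    ev_chan <<- c(ev_chan, chan); ev_dtime <<- c(ev_dtime, dtime)
    ev_t <<- c(ev_t, t)
  }
  t <- 0
  add(15, 4, t)  # frame marker (bit 3)
  t <- t + 1
  for (r in seq_len(rows)) {
    add(15, 1, t)  # line start (bit 1)
    line_t0 <- t
    for (cc in seq_len(cols)) {
      px_t <- line_t0 + (cc - 1) * spp + spp %/% 2
      for (i in seq_along(channels)) {
        dec <- channels[[i]][r, cc, ]
        bins <- rep(which(dec > 0), times = dec[dec > 0])
        if (length(bins)) {
          add(rep(i, length(bins)), bins - 1, rep(px_t, length(bins)))
        }
      }
    }
    t <- line_t0 + cols * spp
    add(15, 2, t)  # line stop (bit 2)
    t <- t + 1
  }
  # interleave overflow records so every nsync fits in 16 bits
  ord <- order(ev_t, method = "radix")
  ev_chan <- ev_chan[ord]; ev_dtime <- ev_dtime[ord]; ev_t <- ev_t[ord]
  recs <- numeric(0)
  emitted_wraps <- 0
  out <- vector("list", length(ev_t))
  wraps_needed <- ev_t %/% .ptu_wrap
  rec_vals <- ptu_record(ev_chan, ev_dtime, ev_t %% .ptu_wrap)
  all_vals <- numeric(length(ev_t) + max(wraps_needed, 0))
  pos <- 0L
  for (i in seq_along(ev_t)) {
    while (emitted_wraps < wraps_needed[i]) {
      pos <- pos + 1L
      all_vals[pos] <- ptu_record(15, 0, 0)
      emitted_wraps <- emitted_wraps + 1
    }
    pos <- pos + 1L
    all_vals[pos] <- rec_vals[i]
  }
  all_vals <- all_vals[seq_len(pos)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw(.ptu_magic), raw(2)), con)           # magic, 8 bytes
  writeBin(c(charToRaw("1.0.00"), raw(2)), con)             # version
  tags <- c(
    ptu_tag_raw("TTResultFormat_TTTRRecType", .ptu_ty_int8,
                .ptu_rectype_pht3),
    ptu_tag_raw("TTResultFormat_BitsPerRecord", .ptu_ty_int8, 32),
    ptu_tag_raw("MeasDesc_Resolution", .ptu_ty_float8, bin_width * 1e-9),
    ptu_tag_raw("MeasDesc_GlobalResolution", .ptu_ty_float8,
                1e-6 / rep_frequency),
    ptu_tag_raw("Measurement_Mode", .ptu_ty_int8, 3),      # T3
    ptu_tag_raw("Measurement_SubMode", .ptu_ty_int8, 3),   # image scan
    ptu_tag_raw("TTResult_SyncRate", .ptu_ty_int8,
                round(rep_frequency * 1e6)),
    ptu_tag_raw("ImgHdr_Ident", .ptu_ty_int8, 3),          # LSM scanner
    ptu_tag_raw("ImgHdr_Dimensions", .ptu_ty_int8, 3),
    ptu_tag_raw("ImgHdr_PixX", .ptu_ty_int8, cols),
    ptu_tag_raw("ImgHdr_PixY", .ptu_ty_int8, rows),
    ptu_tag_raw("ImgHdr_LineStart", .ptu_ty_int8, 1),
    ptu_tag_raw("ImgHdr_LineStop", .ptu_ty_int8, 2),
    ptu_tag_raw("ImgHdr_Frame", .ptu_ty_int8, 3),
    ptu_tag_raw("TTResult_NumberOfRecords", .ptu_ty_int8, length(all_vals)),
    ptu_tag_raw("Header_End", .ptu_ty_empty8, 0))
  writeBin(tags, con)
  signed <- ifelse(all_vals > 2^31 - 1, all_vals - 2^32, all_vals)
  writeBin(as.integer(signed), con, size = 4, endian = "little")
  invisible(path)
}
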