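# Static figures: phasor plots (scatter / 2-D histogram / KDE contour with
# the universal circle), lifetime and intensity maps with colorbars,
# galleries with a shared scale, and violin plots of per-image means.
# Base graphics only, so rendering is deterministic given identical input.

#' Plot style settings
#'
#' @param mode phasor-cloud rendering: `"scatter"`, `"histogram2d"` or
#'   `"contour"` (Gaussian KDE, Scott's-rule bandwidth, levels at 25/50/75/
#'   95 % of peak density).
#' @param colormap palette name understood by [grDevices::hcl.colors()].
#' @param lifetime_range `c(min, max)` ns for map colour scaling, or `NULL`
#'   for the 2-98 % percentile of valid pixels.
#' @param point_alpha scatter-point opacity in `[0, 1]`.
#' @param condition_colors named character vector mapping condition to
#'   colour; unknown conditions draw from a default palette.
#' @param bins2d bin count per axis for `histogram2d` mode.
#' @param dpi raster resolution for PNG output.
#' @return an object of class `plot_style`.
#' @export
plot_style <- function(mode = c("scatter", "histogram2d", "contour"),
                       colormap = "Viridis", lifetime_range = NULL,
                       point_alpha = 0.25, condition_colors = NULL,
                       bins2d = 200L, dpi = 300) {
  mode <- match.arg(mode)
  if (!is.null(lifetime_range)) {
    stopifnot(length(lifetime_range) == 2,
              lifetime_range[1] < lifetime_range[2])
  }
  stopifnot(point_alpha >= 0, point_alpha <= 1)
  structure(list(mode = mode, colormap = colormap,
                 lifetime_range = lifetime_range,
                 point_alpha = point_alpha,
                 condition_colors = condition_colors,
                 bins2d = as.integer(bins2d), dpi = dpi),
            class = "plot_style")
}

# vertices of the universal (semi)circle g^2 + s^2 = g
universal_circle <- function(n = 361L) {
  theta <- seq(0, pi, length.out = n)
  cbind(g = 0.5 + 0.5 * cos(theta), s = 0.5 * sin(theta))
}

condition_palette <- function(conditions, style) {
  cols <- grDevices::hcl.colors(max(3L, length(conditions)), "Dark 3")
  out <- stats::setNames(cols[seq_along(conditions)], conditions)
  if (!is.null(style$condition_colors)) {
    known <- intersect(names(style$condition_colors), conditions)
    out[known] <- style$condition_colors[known]
  }
  out
}

open_device <- function(out_path, width, height, dpi) {
  ext <- tolower(tools::file_ext(out_path))
  switch(ext,
    png = grDevices::png(out_path, width = width, height = height,
                         units = "in", res = dpi, type = "cairo"),
    svg = grDevices::svg(out_path, width = width, height = height),
    stop(sprintf("unsupported figure format: .%s (use png or svg)", ext),
         call. = FALSE))
}

# Scott's rule bandwidth for a 2-D Gaussian KDE (per axis)
scott_bandwidth <- function(x) stats::sd(x) * length(x)^(-1 / 6)

#' Render a phasor plot
#'
#' Draws one layer per pooled condition over the universal circle
#' (monoexponential locus, radius 0.5 centred at (0.5, 0)). Modes: scatter
#' (per-pixel points), 2-D histogram (density heat map of the first point
#' set) or KDE contour (one contour set per condition, Scott's-rule
#' bandwidth, levels at 25/50/75/95 % of each condition's peak density).
#'
#' @param point_sets a `phasor_points` data.frame ([pool_condition()]) or a
#'   list of them, one per condition.
#' @param style a [plot_style()].
#' @param out_path output figure path (`.png` or `.svg`).
#' @return (invisibly) the path.
#' @export
render_phasor_plot <- function(point_sets, style = plot_style(), out_path) {
  if (is.data.frame(point_sets)) point_sets <- list(point_sets)
  conditions <- vapply(point_sets, function(p) {
    if (nrow(p)) as.character(p$condition[1]) else ""
  }, character(1))
  pal <- condition_palette(conditions, style)
  open_device(out_path, 7, 5.2, style$dpi)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4.2, 4.2, 1.5, 1))
  graphics::plot(NA, xlim = c(-0.005, 1.005), ylim = c(0, 0.7),
                 xlab = "G", ylab = "S", asp = 1)
  if (all(!vapply(point_sets, nrow, integer(1)))) {
    warning("empty phasor point set: drawing universal circle only",
            call. = FALSE)
  }
  for (i in seq_along(point_sets)) {
    pts <- point_sets[[i]]
    if (!nrow(pts)) next
    col <- pal[conditions[i]]
    if (style$mode == "scatter") {
      graphics::points(pts$g, pts$s, pch = 16, cex = 0.3,
                       col = grDevices::adjustcolor(col,
                                                    style$point_alpha))
    } else if (style$mode == "histogram2d") {
      gb <- seq(0, 1, length.out = style$bins2d + 1L)
      sb <- seq(0, 0.7, length.out = style$bins2d + 1L)
      cnt <- table(cut(pts$g, gb, include.lowest = TRUE),
                   cut(pts$s, sb, include.lowest = TRUE))
      cnt <- matrix(as.numeric(cnt), nrow = style$bins2d)
      cnt[cnt == 0] <- NA
      graphics::image(x = (gb[-1] + gb[-length(gb)]) / 2,
                      y = (sb[-1] + sb[-length(sb)]) / 2,
                      z = cnt, add = TRUE,
                      col = grDevices::hcl.colors(64, style$colormap))
    } else {  # contour
      h <- c(scott_bandwidth(pts$g), scott_bandwidth(pts$s))
      h[h <= 0 | !is.finite(h)] <- 1e-3
      kd <- MASS::kde2d(pts$g, pts$s, h = h * 4, n = 128,
                        lims = c(-0.05, 1.05, -0.05, 0.75))
      levels <- max(kd$z) * c(0.25, 0.5, 0.75, 0.95)
      graphics::contour(kd, levels = levels, add = TRUE, col = col,
                        drawlabels = FALSE, lwd = 1.5)
    }
  }
  uc <- universal_circle()
  graphics::lines(uc[, "g"], uc[, "s"], lwd = 1.2)
  shown <- conditions[nzchar(conditions)]
  if (length(shown)) {
    graphics::legend("topright", legend = shown, col = pal[shown],
                     pch = 16, bty = "n", cex = 0.85)
  }
  invisible(out_path)
}

map_color_limits <- function(values, style) {
  if (!is.null(style$lifetime_range)) return(style$lifetime_range)
  v <- values[is.finite(values)]
  if (!length(v)) return(c(0, 1))
  q <- stats::quantile(v, c(0.02, 0.98), names = FALSE)
  if (q[1] == q[2]) q <- q + c(-0.5, 0.5)
  q
}

draw_map_panel <- function(m, limits, style, highlight = NULL,
                           title = NULL, accent = "#FF3399") {
  pal <- grDevices::hcl.colors(256, style$colormap)
  mm <- pmin(pmax(m, limits[1]), limits[2])
  # image() draws x rightwards, y upwards: transpose and flip rows so that
  # row 1 of the matrix is the top of the displayed image
  z <- t(mm[nrow(mm):1, , drop = FALSE])
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = z,
                  zlim = limits, col = pal, axes = FALSE, xlab = "",
                  ylab = "", asp = 1, useRaster = FALSE)
  if (!is.null(highlight) && any(highlight)) {
    idx <- which(highlight[nrow(highlight):1, , drop = FALSE],
                 arr.ind = TRUE)
    graphics::points(idx[, 2], idx[, 1], pch = 15, col = accent,
                     cex = 28 / max(dim(m)))
  }
  if (!is.null(title)) graphics::title(main = title, cex.main = 0.9)
  graphics::box()
}

draw_colorbar <- function(limits, style, label = "lifetime (ns)") {
  pal <- grDevices::hcl.colors(256, style$colormap)
  ticks <- pretty(limits, 5)
  graphics::image(x = c(0, 1), y = seq(limits[1], limits[2],
                                       length.out = 257),
                  z = matrix(seq(limits[1], limits[2], length.out = 256),
                             nrow = 1),
                  zlim = limits, col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(4, at = ticks[ticks >= limits[1] & ticks <= limits[2]],
                 las = 1, cex.axis = 0.8)
  graphics::mtext(label, side = 4, line = 2.2, cex = 0.8)
  graphics::box()
}

#' Render one lifetime map
#'
#' Colour-codes a per-pixel lifetime map; invalid pixels stay background,
#' pixels of an optional `highlight` mask are overdrawn in a fixed accent
#' colour (ROI back-mapping display), and a colorbar in ns is included.
#'
#' @param maps a [lifetimes_from_phasor()] result.
#' @param which `"phase"`, `"mod"` or `"avg"`.
#' @param style a [plot_style()].
#' @param highlight optional logical matrix of pixels to accent.
#' @param out_path output figure path (`.png` or `.svg`).
#' @param title optional panel title.
#' @return (invisibly) the path.
#' @export
render_lifetime_map <- function(maps, which = c("mod", "phase", "avg"),
                                style = plot_style(), highlight = NULL,
                                out_path, title = NULL) {
  which <- match.arg(which)
  m <- maps[[paste0("tau_", which)]]
  limits <- map_color_limits(m, style)
  open_device(out_path, 6.4, 5, style$dpi)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1, 2), widths = c(5, 1))
  graphics::par(mar = c(1, 1, 2, 1))
  draw_map_panel(m, limits, style, highlight = highlight, title = title)
  graphics::par(mar = c(1, 1, 2, 3.5))
  draw_colorbar(limits, style)
  invisible(out_path)
}

#' Render a gallery of lifetime or intensity maps
#'
#' Grid of per-sample panels (3 columns, `ceiling(n/3)` rows) with the
#' sample id as caption. Lifetime galleries share one colour scale across
#' all panels (the union 2-98 % percentile range unless the style fixes
#' one), so panels are directly comparable; intensity galleries are scaled
#' per panel.
#'
#' @param items named list of matrices (lifetime maps in ns or photon
#'   counts); names are the captions.
#' @param kind `"lifetime"` or `"intensity"`.
#' @param style a [plot_style()].
#' @param out_path output figure path.
#' @return (invisibly) the path.
#' @export
render_gallery <- function(items, kind = c("lifetime", "intensity"),
                           style = plot_style(), out_path) {
  kind <- match.arg(kind)
  stopifnot(length(items) >= 1)
  n <- length(items)
  ncol_g <- min(3L, n)
  nrow_g <- ceiling(n / 3)
  shared <- if (kind == "lifetime") {
    map_color_limits(unlist(lapply(items, as.vector)), style)
  } else NULL
  open_device(out_path, 2.6 * ncol_g + 1, 2.6 * nrow_g, style$dpi)
  on.exit(grDevices::dev.off())
  lay <- cbind(matrix(seq_len(nrow_g * ncol_g), nrow_g, ncol_g,
                      byrow = TRUE), nrow_g * ncol_g + 1L)
  graphics::layout(lay, widths = c(rep(2.6, ncol_g), 1))
  graphics::par(mar = c(0.6, 0.6, 1.8, 0.6))
  for (i in seq_len(nrow_g * ncol_g)) {
    if (i <= n) {
      m <- items[[i]]
      limits <- if (is.null(shared)) map_color_limits(m, style) else shared
      draw_map_panel(m, limits, style, title = names(items)[i])
    } else {
      graphics::plot.new()
    }
  }
  graphics::par(mar = c(0.6, 0.6, 1.8, 3.2))
  draw_colorbar(if (is.null(shared)) map_color_limits(items[[1]], style)
                else shared, style,
                label = if (kind == "lifetime") "lifetime (ns)"
                        else "photons")
  invisible(out_path)
}

#' Violin-plot data and figure for per-image means
#'
#' One violin per condition built from the per-image mean lifetimes of the
#' chosen metric, with the median and interquartile range drawn as lines
#' (quantiles use R's default type-7 linear interpolation). The underlying
#' values are returned so external statistics can reproduce the figure
#' exactly; conditions with no records are skipped with a warning.
#'
#' @param summaries data.frame of [summarize_lifetimes()] records.
#' @param metric `"mod"`, `"phase"` or `"avg"`.
#' @param style a [plot_style()].
#' @param out_path optional figure path; `NULL` skips rendering.
#' @return (invisibly) list with `values` (named list of per-condition
#'   vectors), `stats` (data.frame of n/median/q25/q75) and `path`.
#' @export
violin_data <- function(summaries, metric = c("mod", "phase", "avg"),
                        style = plot_style(), out_path = NULL) {
  metric <- match.arg(metric)
  col <- paste0("mean_tau_", metric, "_ns")
  df <- as.data.frame(summaries)
  conditions <- unique(df$condition)
  values <- list()
  for (cond in conditions) {
    v <- df[[col]][df$condition == cond & !is.na(df[[col]])]
    if (!length(v)) {
      warning(sprintf("condition '%s' has no records: skipped", cond),
              call. = FALSE)
      next
    }
    values[[cond]] <- v
  }
  if (!length(values)) stop("no plottable conditions", call. = FALSE)
  st <- data.frame(
    condition = names(values),
    n = vapply(values, length, integer(1)),
    median = vapply(values, stats::median, numeric(1)),
    q25 = vapply(values, stats::quantile, numeric(1), probs = 0.25,
                 names = FALSE),
    q75 = vapply(values, stats::quantile, numeric(1), probs = 0.75,
                 names = FALSE),
    row.names = NULL)
  if (!is.null(out_path)) {
    pal <- condition_palette(names(values), style)
    open_device(out_path, 1.6 + 1.4 * length(values), 4.6, style$dpi)
    on.exit(grDevices::dev.off())
    rng <- range(unlist(values))
    pad <- diff(rng) * 0.15 + 1e-3
    graphics::par(mar = c(4.5, 4.5, 1, 1))
    graphics::plot(NA, xlim = c(0.5, length(values) + 0.5),
                   ylim = rng + c(-pad, pad), xaxt = "n",
                   xlab = "", ylab = sprintf("mean tau_%s (ns)", metric))
    graphics::axis(1, at = seq_along(values), labels = names(values),
                   las = 2, cex.axis = 0.85)
    for (i in seq_along(values)) {
      v <- values[[i]]
      if (length(v) > 1 && stats::sd(v) > 0) {
        de <- stats::density(v)
        w <- de$y / max(de$y) * 0.38
        graphics::polygon(c(i - w, rev(i + w)), c(de$x, rev(de$x)),
                          col = grDevices::adjustcolor(pal[i], 0.5),
                          border = pal[i])
      } else {
        graphics::segments(i - 0.25, v[1], i + 0.25, v[1], col = pal[i],
                           lwd = 2)
      }
      graphics::segments(i - 0.2, st$median[i], i + 0.2, st$median[i],
                         lwd = 2)
      graphics::segments(i, st$q25[i], i, st$q75[i], lwd = 1.2)
      graphics::points(rep(i, length(v)) +
                         seq(-0.08, 0.08, length.out = length(v)),
                       v, pch = 16, cex = 0.5)
    }
  }
  invisible(list(values = values, stats = st, path = out_path))
}
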