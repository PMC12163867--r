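#' Region of interest in phasor space
#'
#' Either a polygon (>= 3 vertices in (g, s) coordinates) or an ellipse
#' (centre, semi-axes, rotation angle). ROIs select phasor-plot points;
#' [select_by_phasor_roi()] maps the selection back to image pixels.
#'
#' @param kind `"polygon"` or `"ellipse"`.
#' @param vertices for polygons: two-column matrix of (g, s) vertices.
#' @param center,semi_axes,angle for ellipses: centre `(g, s)`, semi-axis
#'   lengths (> 0) and rotation angle in radians.
#' @param label text label for the ROI.
#' @return an object of class `phasor_roi`.
#' @export
phasor_roi <- function(kind = c("polygon", "ellipse"), vertices = NULL,
                       center = NULL, semi_axes = NULL, angle = 0,
                       label = "roi") {
  kind <- match.arg(kind)
  if (kind == "polygon") {
    vertices <- as.matrix(vertices)
    if (nrow(vertices) < 3 || ncol(vertices) != 2) {
      stop("polygon ROI needs >= 3 (g, s) vertices", call. = FALSE)
    }
    obj <- list(kind = kind, vertices = vertices, label = label)
  } else {
    stopifnot(length(center) == 2, length(semi_axes) == 2)
    if (any(semi_axes <= 0)) {
      stop("ellipse semi-axes must be positive", call. = FALSE)
    }
    obj <- list(kind = kind, center = as.numeric(center),
                semi_axes = as.numeric(semi_axes), angle = angle,
                label = label)
  }
  structure(obj, class = "phasor_roi")
}

#' Load phasor ROIs from a JSON file
#'
#' The file holds a list of objects with fields `kind`, `label` and either
#' `vertices` (n x 2) or `center`/`semi_axes`/`angle`.
#'
#' @param path JSON file path.
#' @return list of [phasor_roi()] objects.
#' @export
read_rois <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(spec)) spec <- split(spec, seq_len(nrow(spec)))
  lapply(spec, function(r) {
    if (identical(r$kind, "polygon")) {
      v <- r$vertices
      # jsonlite yields a matrix (rows = vertices) or a list of pairs
      if (!is.matrix(v)) v <- do.call(rbind, lapply(v, unlist))
      phasor_roi("polygon", vertices = v, label = r$label %||% "roi")
    } else {
      phasor_roi("ellipse", center = unlist(r$center),
                 semi_axes = unlist(r$semi_axes),
                 angle = r$angle %||% 0, label = r$label %||% "roi")
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Boundary-inclusive point-in-polygon (crossing count with explicit
# on-segment test, so vertices and edges count as inside).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # collinear and within the segment's bounding box -> on boundary
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_seg <- abs(cross) <= 1e-12 * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      px >= pmin(x1, x2) - 1e-15 & px <= pmax(x1, x2) + 1e-15 &
      py >= pmin(y1, y2) - 1e-15 & py <= pmax(y1, y2) + 1e-15
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

#' Map a phasor-space ROI back to image pixels
#'
#' A pixel is selected iff it is valid in the field and its calibrated
#' `(g, s)` lies inside or on the boundary of the ROI. A zero-area ROI
#' yields an empty mask with a warning.
#'
#' @param field a calibrated `phasor_field`.
#' @param roi a [phasor_roi()].
#' @return logical matrix, `TRUE` for selected pixels.
#' @export
select_by_phasor_roi <- function(field, roi) {
  stopifnot(inherits(field, "phasor_field"), inherits(roi, "phasor_roi"))
  g <- field$g; s <- field$s
  sel <- matrix(FALSE, nrow(g), ncol(g))
  v <- field$valid & is.finite(g) & is.finite(s)
  if (roi$kind == "polygon") {
    vx <- roi$vertices[, 1]; vy <- roi$vertices[, 2]
    area <- abs(sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)) / 2
    if (area == 0) {
      warning("degenerate (zero-area) ROI: empty selection", call. = FALSE)
      return(sel)
    }
    sel[v] <- points_in_polygon(g[v], s[v], vx, vy)
  } else {
    if (any(roi$semi_axes == 0)) {
      warning("degenerate (zero-area) ROI: empty selection", call. = FALSE)
      return(sel)
    }
    co <- cos(roi$angle); si <- sin(roi$angle)
    dx <- g[v] - roi$center[1]; dy <- s[v] - roi$center[2]
    u <- (dx * co + dy * si) / roi$semi_axes[1]
    w <- (-dx * si + dy * co) / roi$semi_axes[2]
    sel[v] <- u^2 + w^2 <= 1
  }
  sel
}

#' Remove manually excluded pixels from a mask
#'
#' Logical AND of `mask` with the complement of `exclusion`; used to drop
#' e.g. dye aggregates identified on the phasor plot from the statistics.
#'
#' @param mask,exclusion logical matrices of identical shape.
#' @return logical matrix.
#' @export
exclude_pixels <- function(mask, exclusion) {
  if (!all(dim(mask) == dim(exclusion))) {
    stop(sprintf("shape mismatch: mask %dx%d vs exclusion %dx%d",
                 nrow(mask), ncol(mask), nrow(exclusion), ncol(exclusion)),
         call. = FALSE)
  }
  mask & !exclusion
}

#' Per-image / per-ROI / per-condition lifetime summary
#'
#' Pixel-weighted means of the three lifetime maps over the pixels that are
#' in `mask` and valid in the respective map; each valid pixel counts once
#' (the paper's statistics operate on such per-image means, one value per
#' image). An empty selection yields `n_pixels = 0` and `NA` means.
#'
#' @param maps a [lifetimes_from_phasor()] result.
#' @param field the matching `phasor_field` (for photon totals).
#' @param mask logical matrix of pixels to include.
#' @param sample_id,condition text labels for the record.
#' @param scope `"image"`, `"roi"` or `"condition"`.
#' @return one-row data.frame: `sample_id, condition, scope, n_pixels,
#'   n_photons, mean_tau_phase_ns, mean_tau_mod_ns, mean_tau_avg_ns`.
#' @export
summarize_lifetimes <- function(maps, field, mask = NULL,
                                sample_id = "sample", condition = "",
                                scope = c("image", "roi", "condition")) {
  scope <- match.arg(scope)
  stopifnot(inherits(maps, "lifetime_maps"), inherits(field, "phasor_field"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(maps$tau_phase),
                                    ncol(maps$tau_phase))
  if (!all(dim(mask) == dim(maps$tau_phase))) {
    stop("mask shape does not match the lifetime maps", call. = FALSE)
  }
  mn <- function(m) {
    sel <- mask & !is.na(m)
    if (any(sel)) mean(m[sel]) else NA_real_
  }
  sel_any <- mask & maps$valid
  data.frame(
    sample_id = sample_id, condition = condition, scope = scope,
    n_pixels = sum(sel_any),
    n_photons = sum(field$photons[mask & field$valid]),
    mean_tau_phase_ns = mn(maps$tau_phase),
    mean_tau_mod_ns = mn(maps$tau_mod),
    mean_tau_avg_ns = mn(maps$tau_avg),
    stringsAsFactors = FALSE)
}

#' Pool phasor points of one experimental condition
#'
#' Concatenates the masked, valid `(g, s)` points of several calibrated
#' fields into one cloud, tagging each point with its source sample. No
#' per-image re-weighting is applied: every pixel contributes one point,
#' matching the single-cloud display of pooled conditions.
#'
#' @param fields list of calibrated `phasor_field`s at the same omega.
#' @param masks list of logical matrices (or `NULL` entries for all-valid).
#' @param condition condition label.
#' @param sample_ids character vector of source labels.
#' @return data.frame `g, s, photons, sample_id, condition` of class
#'   `phasor_points`.
#' @export
pool_condition <- function(fields, masks = NULL, condition = "",
                           sample_ids = NULL) {
  stopifnot(length(fields) >= 1)
  omegas <- vapply(fields, function(f) f$omega, numeric(1))
  if (max(omegas) - min(omegas) > 1e-12 * max(omegas)) {
    stop("cannot pool phasor fields with different omega", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample%02d", seq_along(fields))
  }
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    sel <- f$valid
    if (!is.null(masks) && !is.null(masks[[i]])) sel <- sel & masks[[i]]
    out[[i]] <- data.frame(g = f$g[sel], s = f$s[sel],
                           photons = f$photons[sel],
                           sample_id = sample_ids[i],
                           condition = condition,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("phasor_points", class(res))
  attr(res, "omega") <- omegas[1]
  res
}

#' Mann-Whitney U test on per-image means
#'
#' Rank-sum comparison of two groups of per-image mean lifetimes (the unit
#' of analysis is the image, not the pixel). For groups of at most 8 values
#' each the two-sided p-value is exact, from the permutation distribution
#' of U over all reassignments of the observed values (ties therefore need
#' no special casing); larger groups use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b numeric vectors (>= 1 value each).
#' @param exact_max largest per-group size for the exact enumeration.
#' @return list with `U` (statistic of `group_a`), `p_value` (two-sided)
#'   and `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 8L) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups need at least one value", call. = FALSE)
  }
  n1 <- length(group_a); n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u_stat <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    # two-sided: outcomes at least as far from the null centre as observed
    p <- mean(abs(u_all - mid) >= abs(u_stat - mid) - 1e-9)
    method <- "exact (permutation enumeration)"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * (nn + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_stat - n1 * n2 / 2)
      z <- (abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = u_stat, p_value = p, method = method, n = c(n1, n2))
}
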