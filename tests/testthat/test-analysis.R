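test_that("phasor ROIs map back to the generating pixels exactly", {
  omega <- angular_frequency(80)
  pattern <- matrix(1L, 8, 8)
  pattern[3:6, 3:6] <- 2L
  comps <- list("1" = data.frame(tau = 1.5, fraction = 1),
                "2" = data.frame(tau = 3.8, fraction = 1))
  spec <- synthetic_spec(shape = c(8, 8), n_bins = 256,
                         photons_per_pixel = 1000)
  cube <- generate_cube(spec, pattern, comps)$cube
  ref <- generate_reference(4, spec)
  cal <- derive_calibration(compute_phasor(ref), 4)
  f <- apply_calibration(compute_phasor(cube), cal)
  p2 <- analytic_phasor(3.8, omega)
  roi <- phasor_roi("ellipse", center = p2, semi_axes = c(0.02, 0.02))
  sel <- select_by_phasor_roi(f, roi)
  expect_equal(unname(sel), unname(pattern == 2L))

  # a polygon covering the whole physical phasor region selects all valid
  all_roi <- phasor_roi("polygon",
                        vertices = rbind(c(-0.1, -0.1), c(1.1, -0.1),
                                         c(1.1, 0.7), c(-0.1, 0.7)))
  expect_equal(select_by_phasor_roi(f, all_roi), f$valid)

  # degenerate ROIs: empty mask with a warning
  line <- phasor_roi("polygon",
                     vertices = rbind(c(0, 0), c(1, 1), c(0.5, 0.5)))
  expect_warning(empty <- select_by_phasor_roi(f, line), "degenerate")
  expect_false(any(empty))
})

test_that("point-in-polygon agrees with an angle-summation oracle", {
  # independent oracle: winding angle accumulation
  winding_inside <- function(px, py, vx, vy) {
    n <- length(vx)
    total <- 0
    for (i in seq_len(n)) {
      j <- i %% n + 1
      a1 <- atan2(vy[i] - py, vx[i] - px)
      a2 <- atan2(vy[j] - py, vx[j] - px)
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      total <- total + d
    }
    abs(total) > pi
  }
  # non-convex polygon in phasor coordinates
  vx <- c(0.1, 0.9, 0.9, 0.5, 0.1)
  vy <- c(0.05, 0.05, 0.6, 0.25, 0.6)
  set.seed(31)
  px <- runif(1000); py <- runif(1000, 0, 0.7)
  # skip points essentially on an edge, where conventions may differ
  edge_dist <- vapply(seq_along(px), function(k) {
    d <- Inf
    for (i in seq_along(vx)) {
      j <- i %% length(vx) + 1
      ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
      t <- pmin(1, pmax(0, ((px[k] - vx[i]) * ex + (py[k] - vy[i]) * ey) /
                            (ex^2 + ey^2)))
      d <- min(d, sqrt((px[k] - vx[i] - t * ex)^2 +
                         (py[k] - vy[i] - t * ey)^2))
    }
    d
  }, numeric(1))
  keep <- edge_dist > 1e-6
  f <- field_from_gs(matrix(px, 1), matrix(py, 1))
  roi <- phasor_roi("polygon", vertices = cbind(vx, vy))
  got <- select_by_phasor_roi(f, roi)[1, ]
  want <- vapply(seq_along(px), function(k)
    winding_inside(px[k], py[k], vx, vy), logical(1))
  expect_equal(got[keep], want[keep])
  # vertices and edge midpoints are boundary-inclusive
  bx <- c(vx, (vx + vx[c(2:5, 1)]) / 2)
  by <- c(vy, (vy + vy[c(2:5, 1)]) / 2)
  fb <- field_from_gs(matrix(bx, 1), matrix(by, 1))
  expect_true(all(select_by_phasor_roi(fb, roi)))
})

test_that("ROI selection is idempotent", {
  f <- calibrated_mono_field(3, tau_ref = 4, shape = c(6, 6))
  roi <- phasor_roi("ellipse", center = c(f$g[1, 1], f$s[1, 1]),
                    semi_axes = c(0.05, 0.05))
  m1 <- select_by_phasor_roi(f, roi)
  f2 <- f; f2$valid <- f2$valid & m1
  expect_equal(select_by_phasor_roi(f2, roi), m1)
})

test_that("exclusion masks are a logical AND-NOT", {
  set.seed(32)
  m <- matrix(runif(30) > 0.4, 5, 6)
  ex <- matrix(runif(30) > 0.6, 5, 6)
  got <- exclude_pixels(m, ex)
  for (i in seq_len(30)) expect_equal(got[i], m[i] && !ex[i])
  expect_equal(exclude_pixels(m, matrix(FALSE, 5, 6)), m)
  expect_false(any(exclude_pixels(m, m)))
  expect_error(exclude_pixels(m, matrix(TRUE, 6, 5)), "shape mismatch")
})

test_that("summaries are pixel-weighted means over the masked valid set", {
  f <- field_from_gs(matrix(0.5, 4, 4), matrix(0.4, 4, 4))
  maps <- lifetimes_from_phasor(f)
  maps$tau_phase[] <- 2.5; maps$tau_mod[] <- 2.5; maps$tau_avg[] <- 2.5
  rec <- summarize_lifetimes(maps, f, sample_id = "u", condition = "c")
  expect_equal(rec$mean_tau_phase_ns, 2.5)
  expect_equal(rec$n_pixels, 16)
  expect_equal(rec$scope, "image")

  # two halves at 2 and 4 ns: pixel-weighted mean is 3.0
  maps$tau_mod[, 1:2] <- 2; maps$tau_mod[, 3:4] <- 4
  rec2 <- summarize_lifetimes(maps, f)
  expect_equal(rec2$mean_tau_mod_ns, 3.0)

  # random map against a brute-force mean over the masked entries
  set.seed(33)
  maps$tau_mod[] <- runif(16, 1, 5)
  maps$tau_mod[2, 2] <- NA
  mask <- matrix(runif(16) > 0.3, 4, 4)
  rec3 <- summarize_lifetimes(maps, f, mask)
  sel <- mask & !is.na(maps$tau_mod)
  expect_equal(rec3$mean_tau_mod_ns, mean(maps$tau_mod[sel]))

  # empty selection: zero pixels, absent means
  rec4 <- summarize_lifetimes(maps, f, matrix(FALSE, 4, 4))
  expect_equal(rec4$n_pixels, 0)
  expect_true(is.na(rec4$mean_tau_mod_ns))
})

test_that("condition pooling concatenates masked valid points", {
  f1 <- calibrated_mono_field(2, tau_ref = 4, shape = c(3, 3))
  f2 <- calibrated_mono_field(3.5, tau_ref = 4, shape = c(4, 4))
  m1 <- matrix(TRUE, 3, 3); m1[1, ] <- FALSE
  pool1 <- pool_condition(list(f1), list(m1), condition = "ctrl")
  expect_equal(nrow(pool1), 6)
  expect_equal(pool1$g, f1$g[m1])
  pool <- pool_condition(list(f1, f2), list(m1, NULL), condition = "ctrl",
                         sample_ids = c("a", "b"))
  expect_equal(nrow(pool), 6 + 16)
  expect_equal(unique(pool$condition), "ctrl")
  # pooled mean equals the size-weighted mean of per-image means
  per_image <- c(mean(f1$g[m1]), mean(f2$g))
  sizes <- c(6, 16)
  expect_equal(mean(pool$g), sum(per_image * sizes) / sum(sizes),
               tolerance = 1e-12)
  f_bad <- f2; f_bad$omega <- f2$omega * 2
  expect_error(pool_condition(list(f1, f_bad)), "different omega")
})

test_that("pooled-condition mean decomposes over per-image summaries", {
  maps_list <- list(); recs <- list()
  fields <- list()
  set.seed(34)
  for (k in 1:3) {
    f <- field_from_gs(matrix(runif(9, 0.3, 0.6), 3),
                       matrix(runif(9, 0.2, 0.45), 3))
    maps <- lifetimes_from_phasor(f)
    fields[[k]] <- f; maps_list[[k]] <- maps
    recs[[k]] <- summarize_lifetimes(maps, f, sample_id = paste0("s", k),
                                     condition = "c")
  }
  recs <- do.call(rbind, recs)
  pooled_mean <- sum(recs$mean_tau_mod_ns * recs$n_pixels) /
    sum(recs$n_pixels)
  all_vals <- unlist(lapply(maps_list, function(m) m$tau_mod[m$valid]))
  expect_equal(pooled_mean, mean(all_vals), tolerance = 1e-12)
})

test_that("masking order does not matter", {
  cube <- random_cube(5, 5, 16, seed = 35)
  manual <- matrix(rep(c(TRUE, FALSE), length.out = 25), 5, 5)
  thr <- apply_photon_threshold(cube, 300, 340)
  expect_equal(thr & manual, exclude_pixels(manual, !thr))
})

test_that("Mann-Whitney helper: exact enumeration and approximation", {
  # identical groups: exact method, p = 1
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_match(r$method, "exact")
  expect_equal(r$p_value, 1)
  # complete separation of 3 vs 3: U = 0, two-sided p = 2/20
  r2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p_value, 0.1)
  # tie-free random cases match wilcox.test's exact p
  set.seed(36)
  for (k in 1:5) {
    a <- sample(1:100, 5); b <- sample(1:100, 6) + 0.25  # tie-free
    r3 <- mann_whitney(a, b)
    w <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(r3$U, unname(w$statistic))
    expect_equal(r3$p_value, w$p.value, tolerance = 1e-12)
  }
  # large groups: normal approximation matches wilcox.test with ties
  set.seed(37)
  a <- round(rnorm(17, 3.4, 0.1), 2)
  b <- round(rnorm(17, 3.5, 0.1), 2)
  r4 <- mann_whitney(a, b)
  expect_match(r4$method, "normal")
  w4 <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  expect_equal(r4$p_value, w4$p.value, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1), "at least one")
})

test_that("exact Mann-Whitney agrees with a pair-counting enumeration", {
  # oracle: U as the count of (a, b) pairs with a > b (+ half ties),
  # permutation distribution enumerated over explicit assignments
  oracle <- function(a, b) {
    pooled <- c(a, b); n1 <- length(a)
    u_of <- function(x, y) {
      sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    }
    u_obs <- u_of(a, b)
    combos <- utils::combn(length(pooled), n1)
    mid <- n1 * length(b) / 2
    u_all <- apply(combos, 2, function(idx)
      u_of(pooled[idx], pooled[-idx]))
    list(U = u_obs,
         p = mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9))
  }
  set.seed(38)
  cases <- list(
    list(a = c(1, 1, 2), b = c(2, 3, 3)),          # ties across groups
    list(a = rnorm(4), b = rnorm(5)),
    list(a = sample(1:10, 6, TRUE), b = sample(1:10, 6, TRUE)),
    list(a = c(5), b = c(1, 2, 3)))
  for (cs in cases) {
    got <- mann_whitney(cs$a, cs$b)
    want <- oracle(cs$a, cs$b)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p)
  }
})

test_that("ROIs load from JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(kind = "polygon", label = "main",
         vertices = list(c(0.2, 0.1), c(0.8, 0.1), c(0.5, 0.5))),
    list(kind = "ellipse", label = "agg", center = c(0.7, 0.3),
         semi_axes = c(0.05, 0.03), angle = 0.2)),
    p, auto_unbox = TRUE, digits = NA)
  rois <- read_rois(p)
  expect_length(rois, 2)
  expect_equal(rois[[1]]$kind, "polygon")
  expect_equal(nrow(rois[[1]]$vertices), 3)
  expect_equal(rois[[2]]$semi_axes, c(0.05, 0.03))
  expect_error(phasor_roi("polygon", vertices = rbind(c(0, 0), c(1, 1))),
               ">= 3")
  expect_error(phasor_roi("ellipse", center = c(0, 0),
                          semi_axes = c(0, 0.1)), "positive")
})
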