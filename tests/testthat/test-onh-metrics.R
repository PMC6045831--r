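test_that("BM bridging is a straight line continuous at both junctions", {
  sc <- make_scan(axial = 4, lateral = 10)  # 600 cols -> width 5990 um
  # flat case: both margins at the same depth -> horizontal bridge
  seg <- make_flat_seg(sc, bm_row = 87.5)  # 350 um at axial 4
  sb <- bridge_bm(seg, sc, step = 10)
  expect_true(all(abs(sb$ys - 350) < 1e-9))

  # sloped margins: exact chord across the gap
  nc <- ncol(sc$pixels) - 1L
  seg2 <- scan_segmentation(
    sc$scan_id, "R1", "s1",
    ilm = boundary_segment("ILM", cbind(c(0, nc), c(10, 10))),
    bm_left = boundary_segment("BM_left",
                               cbind(c(0, 200), c(75, 75))),     # 300 um
    bm_right = boundary_segment("BM_right",
                                cbind(c(400, nc), c(100, 100)))) # 400 um
  f <- onhrel:::bridged_bm_fun(seg2, sc)
  # margins at (2000 um, 300 um) and (4000 um, 400 um): midpoint 350 um
  expect_equal(f(3000), 350)
  # junction values equal the wing endpoint depths exactly
  expect_equal(f(2000), 300)
  expect_equal(f(4000), 400)
})

test_that("rectangle geometry yields the closed-form area", {
  # flat ILM at 100 um, flat BM at 400 um over a 5.7 mm window: 1.71 mm^2
  sc <- make_scan(rows = 200, cols = 601, axial = 4, lateral = 10)
  seg <- make_flat_seg(sc, ilm_row = 25, bm_row = 100)
  res <- cross_sectional_area(seg, sc, half_width = 2.85, step = 5)
  expect_equal(res$area_mm2, 1.71, tolerance = 1e-9)
  expect_equal(res$window_half_width_mm, 2.85)

  # coincident boundaries -> zero area
  seg0 <- make_flat_seg(sc, ilm_row = 100, bm_row = 100)
  expect_equal(cross_sectional_area(seg0, sc)$area_mm2, 0,
               tolerance = 1e-12)

  # window wider than the boundary support errors
  expect_error(cross_sectional_area(seg, sc, half_width = 3.5),
               "window exceeds")
})

test_that("crossing boundaries keep the signed integrand and warn", {
  sc <- make_scan(rows = 200, cols = 601, axial = 4, lateral = 10)
  seg <- make_flat_seg(sc, ilm_row = 120, bm_row = 100)  # ILM below BM
  expect_warning(res <- cross_sectional_area(seg, sc), "signed")
  expect_lt(res$area_mm2, 0)
})

test_that("area matches the analytic phantom oracle", {
  spec <- phantom_spec(baseline_ilm_depth = 700, bump_amplitude = 400,
                       bump_sigma = 700, bm_depth = 1010,
                       bm_gap_half_width = 600, scan_half_width = 2850)
  sc <- make_phantom_scan(spec)
  seg <- make_truth_seg(spec, sc, spacing = 100)
  res <- cross_sectional_area(seg, sc, half_width = 2.85, step = 5)
  expect_equal(res$area_mm2, analytic_area(spec, 2.85), tolerance = 1e-3)
})

test_that("area is additive over adjacent windows", {
  spec <- phantom_spec(bump_amplitude = 300, scan_half_width = 2850)
  sc <- make_phantom_scan(spec)
  seg <- make_truth_seg(spec, sc)
  ctr <- scan_width_um(sc) / 2
  w <- 2
  full <- cross_sectional_area(seg, sc, half_width = w, step = 5)$area_mm2
  left <- cross_sectional_area(seg, sc, half_width = w / 2, step = 5,
                               center_x = ctr - w * 500)$area_mm2
  right <- cross_sectional_area(seg, sc, half_width = w / 2, step = 5,
                                center_x = ctr + w * 500)$area_mm2
  expect_equal(left + right, full, tolerance = 1e-12)
})

test_that("halving the integration step barely changes a smooth area", {
  spec <- phantom_spec(bump_amplitude = 500, scan_half_width = 2850)
  sc <- make_phantom_scan(spec)
  seg <- make_truth_seg(spec, sc)
  a5 <- cross_sectional_area(seg, sc, step = 5)$area_mm2
  a2.5 <- cross_sectional_area(seg, sc, step = 2.5)$area_mm2
  expect_lt(abs(a5 - a2.5) / a2.5, 5e-4)
})

test_that("area obeys the axial translation laws", {
  sc <- make_scan(rows = 300, cols = 601, axial = 4, lateral = 10)
  seg <- make_flat_seg(sc, ilm_row = 25, bm_row = 100)
  base <- cross_sectional_area(seg, sc)$area_mm2
  # shifting both boundaries by a constant leaves the area unchanged
  shift_seg <- function(s, d_ilm, d_bm) {
    s$ilm$points[, 2] <- s$ilm$points[, 2] + d_ilm
    s$bm_left$points[, 2] <- s$bm_left$points[, 2] + d_bm
    s$bm_right$points[, 2] <- s$bm_right$points[, 2] + d_bm
    s
  }
  both <- shift_seg(seg, 12.5, 12.5)  # 50 um at axial 4
  expect_equal(cross_sectional_area(both, sc)$area_mm2, base,
               tolerance = 1e-12)
  # shifting BM alone by delta changes the area by exactly 2 w delta
  delta_px <- 10  # 40 um = 0.04 mm
  one <- shift_seg(seg, 0, delta_px)
  expect_equal(cross_sectional_area(one, sc)$area_mm2 - base,
               2 * 2.85 * 0.04, tolerance = 1e-12)
})

test_that("segmentation difference matches a brute-force column loop", {
  set.seed(21)
  sc <- make_scan(rows = 300, cols = 601, axial = 4, lateral = 10)
  jitter_seg <- function(seed) {
    set.seed(seed)
    s <- make_flat_seg(sc, ilm_row = 25, bm_row = 100, n_pts = 9)
    s$ilm$points[, 2] <- s$ilm$points[, 2] + rnorm(9, 0, 3)
    s$bm_left$points[, 2] <- s$bm_left$points[, 2] + rnorm(7, 0, 3)
    s$bm_right$points[, 2] <- s$bm_right$points[, 2] + rnorm(7, 0, 3)
    s
  }
  a <- jitter_seg(1); b <- jitter_seg(2)
  d <- segmentation_difference(a, b, "ILM", sc, step = 10)
  # independent oracle: explicit loop over grid positions
  xs <- seq(0, 6000, by = 10); xs <- xs[xs <= scan_width_um(sc)]
  acc <- 0
  for (x in xs) {
    ya <- fit_boundary(a$ilm, x / sc$lateral_scale) * sc$axial_scale
    yb <- fit_boundary(b$ilm, x / sc$lateral_scale) * sc$axial_scale
    acc <- acc + abs(ya - yb)
  }
  expect_equal(d$mean_abs_diff_um, acc / length(xs), tolerance = 1e-9)
  expect_equal(d$mean_abs_diff_px, d$mean_abs_diff_um / sc$axial_scale)
})

test_that("segmentation difference is a pseudometric", {
  sc <- make_scan(rows = 300, cols = 601, axial = 4, lateral = 10)
  segs <- lapply(1:3, function(i) {
    set.seed(30 + i)
    s <- make_flat_seg(sc, ilm_row = 25, bm_row = 100, n_pts = 9)
    s$ilm$points[, 2] <- s$ilm$points[, 2] + rnorm(9, 0, 4)
    s
  })
  d <- function(a, b)
    segmentation_difference(a, b, "ILM", sc, step = 20)$mean_abs_diff_um
  expect_equal(d(segs[[1]], segs[[1]]), 0)
  expect_equal(d(segs[[1]], segs[[2]]), d(segs[[2]], segs[[1]]))
  expect_lte(d(segs[[1]], segs[[3]]),
             d(segs[[1]], segs[[2]]) + d(segs[[2]], segs[[3]]) + 1e-12)
})

test_that("constant axial offset between raters is recovered exactly", {
  sc <- make_scan(rows = 300, cols = 601, axial = 4, lateral = 10)
  a <- make_flat_seg(sc)
  b <- make_flat_seg(sc, rater_id = "R2")
  b$ilm$points[, 2] <- b$ilm$points[, 2] + 1.25  # 5 um at axial 4
  expect_equal(
    segmentation_difference(a, b, "ILM", sc)$mean_abs_diff_um, 5,
    tolerance = 1e-12)
  # BM comparisons use the bridged boundary, including the sub-nerve line
  b2 <- make_flat_seg(sc, rater_id = "R2")
  b2$bm_left$points[, 2] <- b2$bm_left$points[, 2] + 2.5
  b2$bm_right$points[, 2] <- b2$bm_right$points[, 2] + 2.5
  expect_equal(
    segmentation_difference(a, b2, "BM", sc)$mean_abs_diff_um, 10,
    tolerance = 1e-12)
  # mismatched scans refuse to compare
  other <- make_flat_seg(sc, scan_id = "other")
  expect_error(segmentation_difference(a, other, "ILM", sc), "same scan")
})
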