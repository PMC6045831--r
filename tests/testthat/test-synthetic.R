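test_that("phantom truth has the specified peak, symmetry and flat limits", {
  spec <- phantom_spec(baseline_ilm_depth = 700, bump_amplitude = 200,
                       bump_sigma = 700, bm_depth = 1000)
  ctr <- spec$center_x
  tr <- phantom_truth(spec, ctr)
  expect_equal(tr$y_ilm, 700 - 200)  # peak elevation at the centre
  expect_true(is.na(tr$y_bm))        # centre is inside the BM gap
  # symmetry about the centre
  d <- c(100, 500, 1500)
  expect_equal(phantom_truth(spec, ctr + d)$y_ilm,
               phantom_truth(spec, ctr - d)$y_ilm)
  # amplitude 0 -> flat ILM at baseline
  flat <- phantom_spec(bump_amplitude = 0)
  xs <- seq(0, 2 * flat$scan_half_width, by = 250)
  expect_true(all(phantom_truth(flat, xs)$y_ilm == flat$baseline_ilm_depth))
  # BM is flat outside the gap, undefined inside
  tb <- phantom_truth(spec, ctr + c(0, 499, 501, 2000))$y_bm
  expect_true(all(is.na(tb[1:2])))
  expect_true(all(tb[3:4] == 1000))
  expect_error(phantom_truth(spec, -10), "outside")
})

test_that("analytic area reduces to the rectangle for amplitude zero", {
  spec <- phantom_spec(baseline_ilm_depth = 100, bump_amplitude = 0,
                       bm_depth = 400)
  expect_equal(analytic_area(spec, 2.85), 1.71)
  # continuity as amplitude -> 0
  eps <- phantom_spec(baseline_ilm_depth = 100, bump_amplitude = 1e-6,
                      bm_depth = 400)
  expect_equal(analytic_area(eps, 2.85), 1.71, tolerance = 1e-8)
})

test_that("analytic area matches numerical quadrature to 6 significant figures", {
  set.seed(51)
  for (rep in 1:10) {
    spec <- phantom_spec(baseline_ilm_depth = runif(1, 650, 750),
                         bump_amplitude = runif(1, 0, 600),
                         bump_sigma = runif(1, 400, 1000),
                         bm_depth = runif(1, 950, 1100),
                         bm_gap_half_width = 500, scan_half_width = 2850)
    hw <- runif(1, 1, 2.85)
    num <- stats::integrate(function(x) {
      spec$bm_depth - phantom_truth(spec, x)$y_ilm
    }, spec$center_x - hw * 1000, spec$center_x + hw * 1000,
    rel.tol = 1e-10)$value * 1e-6
    expect_equal(analytic_area(spec, hw), num, tolerance = 1e-6)
  }
})

test_that("a noise-free rater reproduces the truth at control points", {
  spec <- phantom_spec(bump_amplitude = 300)
  sc <- make_phantom_scan(spec)
  seg <- make_truth_seg(spec, sc)
  cols <- seg$ilm$points[, 1]
  truth <- phantom_truth(spec, cols * sc$lateral_scale)$y_ilm
  expect_equal(seg$ilm$points[, 2] * sc$axial_scale, truth,
               tolerance = 1e-9)
  expect_equal(unique(seg$bm_left$points[, 2]) * sc$axial_scale,
               spec$bm_depth)
})

test_that("simulated raters are deterministic given their seeds", {
  spec <- phantom_spec(bump_amplitude = 300)
  sc <- make_phantom_scan(spec)
  model <- rater_model("R1")
  s1 <- simulate_rater(spec, sc, model, seed = 99, rater_seed = 7)
  s2 <- simulate_rater(spec, sc, model, seed = 99, rater_seed = 7)
  expect_equal(s1, s2)
  s3 <- simulate_rater(spec, sc, model, seed = 100, rater_seed = 7)
  expect_false(isTRUE(all.equal(s1$ilm$points, s3$ilm$points)))
  # rater-level error is shared across sessions: session-to-session
  # differences are much smaller than the rater-level sd
  d <- segmentation_difference(s1, s3, "ILM", sc)
  expect_lt(d$mean_abs_diff_um, 3 * model$session_noise_sd * 2)
})

test_that("two raters' mean absolute ILM difference follows the folded normal", {
  # with axial noise sd sigma per rater and no session noise, the pointwise
  # difference is N(0, 2 sigma^2), whose absolute mean is 2 sigma / sqrt(pi)
  spec <- phantom_spec(bump_amplitude = 300)
  sc <- make_phantom_scan(spec)
  sigma <- 8
  mk <- function(id) rater_model(id, axial_noise_sd = sigma,
                                 session_noise_sd = 0)
  diffs <- vapply(1:30, function(i) {
    a <- simulate_rater(spec, sc, mk("A"), seed = 1000 + i,
                        rater_seed = 2000 + i)
    b <- simulate_rater(spec, sc, mk("B"), seed = 3000 + i,
                        rater_seed = 4000 + i)
    segmentation_difference(a, b, "ILM", sc)$mean_abs_diff_um
  }, 0)
  expect_equal(mean(diffs), 2 * sigma / sqrt(pi), tolerance = 0.15)
})

test_that("gross boundary confusion offsets the whole ILM", {
  spec <- phantom_spec(bump_amplitude = 300)
  sc <- make_phantom_scan(spec)
  clean <- rater_model("R1", axial_noise_sd = 0, session_noise_sd = 0,
                       margin_noise_sd = 0)
  confused <- rater_model("R1", axial_noise_sd = 0, session_noise_sd = 0,
                          margin_noise_sd = 0, confusion_prob = 1,
                          confusion_offset = 60)
  a <- simulate_rater(spec, sc, clean, seed = 5)
  b <- simulate_rater(spec, sc, confused, seed = 5)
  expect_equal(segmentation_difference(a, b, "ILM", sc)$mean_abs_diff_um,
               60, tolerance = 1e-9)
})

test_that("device rendering puts boundary bands at the truth depths", {
  spec <- phantom_spec(bump_amplitude = 300)
  dev <- device_model("clean", intensity_noise_sd = 0,
                      systematic_axial_offset = 0)
  sim <- simulate_device(spec, dev, seed = 1)
  img <- sim$scan$pixels
  xs <- (seq_len(ncol(img)) - 1L) * dev$lateral_scale
  truth <- phantom_truth(sim$apparent_spec, xs)
  split_row <- function(j)  # midway between the two bands
    floor((truth$y_ilm[j] + sim$apparent_spec$bm_depth) / 2 /
            dev$axial_scale)
  for (j in c(5, 100, 256, 400)) {
    ilm_peak <- which.max(img[seq_len(split_row(j)), j]) - 1L
    expect_lt(abs(ilm_peak - truth$y_ilm[j] / dev$axial_scale), 1.5)
  }
  # BM band present outside the gap, absent (shadowed) inside it
  for (j in c(5, 400)) {
    lower <- img[(split_row(j) + 1L):nrow(img), j]
    bm_peak <- which.max(lower) + split_row(j) - 1L
    expect_lt(abs(bm_peak - truth$y_bm[j] / dev$axial_scale), 1.5)
  }
  j_gap <- 256  # centre column, inside the sub-nerve gap
  lower <- img[(split_row(j_gap) + 30L):nrow(img), j_gap]
  expect_lt(max(lower), 0.5)
})

test_that("a common axial offset shifts the apparent truth exactly", {
  spec <- phantom_spec(bump_amplitude = 300)
  d0 <- device_model("d0", systematic_axial_offset = 0)
  d30 <- device_model("d30", systematic_axial_offset = 30)
  a0 <- simulate_device(spec, d0, seed = 1)$apparent_spec
  a30 <- simulate_device(spec, d30, seed = 1)$apparent_spec
  expect_equal(a30$baseline_ilm_depth - a0$baseline_ilm_depth, 30)
  expect_equal(a30$bm_depth - a0$bm_depth, 30)
  # and the area is invariant to it
  expect_equal(analytic_area(a30, 2.85), analytic_area(a0, 2.85),
               tolerance = 1e-12)
})

test_that("scale miscalibration rescales measured areas lawfully", {
  # Over a window fixed in reported units, an axial calibration error
  # rescales the whole area by its factor; a lateral error rescales only
  # the elevation-bump contribution (the flat rectangle spans the window
  # regardless of lateral stretch). Both must match the closed form on
  # the apparent geometry.
  spec <- phantom_spec(bump_amplitude = 300, scan_half_width = 2700)
  measure <- function(dev) {
    sim <- simulate_device(spec, dev, seed = 1)
    seg <- make_truth_seg(sim$apparent_spec, sim$scan)
    c(meas = cross_sectional_area(seg, sim$scan, half_width = 2.85,
                                  step = 5)$area_mm2,
      closed = analytic_area(sim$apparent_spec, 2.85))
  }
  base <- measure(device_model("cal", intensity_noise_sd = 0))
  lat <- measure(device_model("lat", intensity_noise_sd = 0,
                              lateral_scale_error = 1.03))
  axi <- measure(device_model("axi", intensity_noise_sd = 0,
                              axial_scale_error = 1.03))
  expect_equal(axi[["meas"]] / base[["meas"]], 1.03, tolerance = 2e-3)
  expect_equal(lat[["meas"]] / base[["meas"]],
               lat[["closed"]] / base[["closed"]], tolerance = 2e-3)
  expect_gt(lat[["meas"]] / base[["meas"]], 1)  # bump term did grow
  for (m in list(base, lat, axi))
    expect_equal(m[["meas"]], m[["closed"]], tolerance = 1e-3)
  # too-narrow field of view is rejected
  tiny <- device_model("tiny", n_cols = 100)
  expect_error(simulate_device(spec, tiny, seed = 1), "field of view")
})

test_that("generate_study writes the full factorial with exact counts", {
  dir <- file.path(tempdir(), "study_counts")
  unlink(dir, recursive = TRUE)
  m <- generate_study(dir, phantoms = default_phantom_set()[1:3],
                      seed = 5)
  # 3 eyes x 3 devices x (3 raters + 1 repeat session)
  expect_equal(nrow(m), 3 * 3 * 4)
  expect_length(list.files(file.path(dir, "scans"), pattern = "\\.tif$"),
                9)
  expect_length(list.files(file.path(dir, "segmentations")), 36)
  expect_true(all(file.exists(file.path(dir, m$seg_file))))
  # same seed reproduces the manifest byte for byte
  dir2 <- file.path(tempdir(), "study_counts2")
  unlink(dir2, recursive = TRUE)
  generate_study(dir2, phantoms = default_phantom_set()[1:3], seed = 5)
  expect_identical(readLines(file.path(dir, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
})

test_that("default phantom calibration spans the clinical area range", {
  areas <- vapply(default_phantom_set(), analytic_area, 0,
                  half_width = 2.85)
  expect_true(all(areas >= 1.6 & areas <= 3.4))
  expect_lt(min(areas), 1.7)   # non-swollen end
  expect_gt(max(areas), 3.0)   # swollen end
  # six swollen, four non-swollen
  amps <- vapply(default_phantom_set(), `[[`, 0, "bump_amplitude")
  expect_equal(sum(amps > 0), 6)
  expect_equal(sum(amps == 0), 4)
})
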