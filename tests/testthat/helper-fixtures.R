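# Fixture builders shared across the suite. Everything is generated in
# code; no binary data ships with the package.

# A blank scan with the given geometry.
make_scan <- function(rows = 200, cols = 600, axial = 4, lateral = 10,
                      scan_id = "scanA", ...) {
  bscan(matrix(0.5, rows, cols), axial_scale = axial,
        lateral_scale = lateral, scan_id = scan_id, ...)
}

# Segmentation with flat boundaries at fixed pixel rows; gap half-width
# and margin positions in pixel columns relative to the scan centre.
make_flat_seg <- function(scan, ilm_row = 25, bm_row = 100,
                          gap_half_px = 50, n_pts = 13,
                          scan_id = scan$scan_id, rater_id = "R1",
                          session_id = "s1") {
  nc <- ncol(scan$pixels) - 1L
  ctr <- nc / 2
  xs_ilm <- seq(0, nc, length.out = n_pts)
  xl <- ctr - gap_half_px
  xr <- ctr + gap_half_px
  scan_segmentation(
    scan_id, rater_id, session_id,
    ilm = boundary_segment("ILM", cbind(xs_ilm, rep(ilm_row, n_pts))),
    bm_left = boundary_segment(
      "BM_left", cbind(seq(0, xl, length.out = 7), rep(bm_row, 7))),
    bm_right = boundary_segment(
      "BM_right", cbind(seq(xr, nc, length.out = 7), rep(bm_row, 7))))
}

# Segmentation tracing a phantom's truth exactly (noise-free rater).
make_truth_seg <- function(spec, scan, spacing = 150, rater_id = "R1",
                           session_id = "s1") {
  noiseless <- rater_model(rater_id, axial_noise_sd = 0,
                           session_noise_sd = 0, margin_noise_sd = 0,
                           control_point_spacing = spacing)
  seg <- simulate_rater(spec, scan, noiseless, seed = 1)
  seg$rater_id <- rater_id
  seg$session_id <- session_id
  seg
}

# Scan sized to carry a phantom at the given scales.
make_phantom_scan <- function(spec, axial = 4, lateral = 10, ...) {
  cols <- as.integer(round(2 * spec$scan_half_width / lateral)) + 1L
  rows <- as.integer(ceiling((spec$bm_depth + 100) / axial)) + 1L
  make_scan(rows = rows, cols = cols, axial = axial, lateral = lateral,
            ...)
}

# Random small ICC tables for oracle comparisons.
random_icc_table <- function(n, k) {
  matrix(stats::rnorm(n * k, mean = rep(stats::rnorm(n, 0, 2), k)),
         nrow = n)
}

# Definitional two-way ANOVA ICC(A,1) oracle via stats::aov mean squares.
icc_oracle_aov <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(seq_len(n), k)),
                   meas = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + meas, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
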