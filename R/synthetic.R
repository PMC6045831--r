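#' Parametric optic-nerve-head phantom
#'
#' Ground-truth geometry for a simulated B-scan: a flat Bruch's membrane at
#' `bm_depth` interrupted by a sub-nerve gap of half-width
#' `bm_gap_half_width` (where the shadowed medial margins leave BM
#' undelineated), and an ILM that rises toward the vitreous as a Gaussian
#' bump of `bump_amplitude` (0 for a non-swollen nerve) and lateral scale
#' `bump_sigma` above a flat baseline at `baseline_ilm_depth`. Depths are
#' measured downward from the top of the image, so elevation means a
#' *smaller* ILM depth at the centre. All fields are in micrometres.
#'
#' @param baseline_ilm_depth flat ILM depth away from the nerve head, um.
#' @param bump_amplitude peak ILM elevation at the centre, um (>= 0).
#' @param bump_sigma lateral standard deviation of the elevation bump, um.
#' @param bm_depth flat BM depth, um (must exceed `baseline_ilm_depth`).
#' @param bm_gap_half_width half-width of the sub-nerve BM gap, um.
#' @param scan_half_width half-width of the scanned region, um.
#' @param center_x lateral position of the nerve-head centre, um; defaults
#'   to `scan_half_width` (centred scan).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(baseline_ilm_depth = 700, bump_amplitude = 0,
                         bump_sigma = 700, bm_depth = 1000,
                         bm_gap_half_width = 500, scan_half_width = 2850,
                         center_x = scan_half_width) {
  if (bm_depth <= baseline_ilm_depth)
    stop("'bm_depth' must be deeper than 'baseline_ilm_depth'")
  if (bump_amplitude < 0) stop("'bump_amplitude' must be >= 0")
  if (bump_amplitude >= baseline_ilm_depth)
    stop("'bump_amplitude' must be smaller than 'baseline_ilm_depth' ",
         "(the elevated ILM must stay inside the image)")
  if (bump_sigma <= 0 || bm_gap_half_width <= 0 || scan_half_width <= 0)
    stop("all widths must be positive")
  if (bm_gap_half_width >= scan_half_width)
    stop("'bm_gap_half_width' must be smaller than 'scan_half_width'")
  structure(list(baseline_ilm_depth = baseline_ilm_depth,
                 bump_amplitude = bump_amplitude, bump_sigma = bump_sigma,
                 bm_depth = bm_depth,
                 bm_gap_half_width = bm_gap_half_width,
                 scan_half_width = scan_half_width, center_x = center_x),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> ILM %g um (bump %g um, sigma %g um), BM %g um, gap +/-%g um, scan +/-%g um\n",
              x$baseline_ilm_depth, x$bump_amplitude, x$bump_sigma,
              x$bm_depth, x$bm_gap_half_width, x$scan_half_width))
  invisible(x)
}

#' Evaluate phantom ground-truth boundaries
#'
#' @param spec a [phantom_spec].
#' @param x lateral positions in um, within
#'   `center_x +/- scan_half_width`.
#' @return List with `y_ilm` and `y_bm` (um depths); `y_bm` is `NA` inside
#'   the sub-nerve gap where BM is not delineated.
#' @export
phantom_truth <- function(spec, x) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(abs(x - spec$center_x) > spec$scan_half_width + 1e-9))
    stop("x outside the scanned region")
  y_ilm <- spec$baseline_ilm_depth -
    spec$bump_amplitude * exp(-(x - spec$center_x)^2 / (2 * spec$bump_sigma^2))
  y_bm <- ifelse(abs(x - spec$center_x) < spec$bm_gap_half_width,
                 NA_real_, spec$bm_depth)
  list(y_ilm = y_ilm, y_bm = y_bm)
}

erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

#' Closed-form phantom cross-sectional area
#'
#' Exact area between the bridged BM (flat, so the bridge coincides with
#' BM) and the Gaussian-bump ILM over a window of `half_width` mm either
#' side of the centre:
#' \deqn{A = 2w(d_{BM} - d_{ILM}) + a\,\sigma\sqrt{2\pi}\,
#'   \mathrm{erf}\!\left(\frac{w}{\sigma\sqrt{2}}\right)}
#' converted to mm^2. Serves as the independent oracle for
#' [cross_sectional_area()].
#'
#' @param spec a [phantom_spec].
#' @param half_width window half-width, mm (<= `scan_half_width`).
#' @return Area in mm^2.
#' @export
analytic_area <- function(spec, half_width = 2.85) {
  stopifnot(inherits(spec, "phantom_spec"))
  hw <- half_width * 1000
  if (hw > spec$scan_half_width + 1e-9)
    stop("'half_width' exceeds the phantom's scan half-width")
  rect <- (spec$bm_depth - spec$baseline_ilm_depth) * 2 * hw
  bump <- spec$bump_amplitude * spec$bump_sigma * sqrt(2 * pi) *
    erf(hw / (spec$bump_sigma * sqrt(2)))
  (rect + bump) * 1e-6
}

#' Simulated rater
#'
#' Noise model for a human rater's boundary placement. Placement error is
#' spatially correlated along the scan (raters misread locally smooth
#' features such as the cup or the sub-nerve shadow, not isolated pixels):
#' each boundary receives a stationary Gaussian-process error with
#' squared-exponential correlation of length `noise_corr_length` and
#' marginal standard deviation `axial_noise_sd`, drawn once per rater and
#' scan and therefore shared between that rater's sessions, plus an
#' independent per-session process of sd `session_noise_sd`. Medial BM
#' margin choice (a rater interpretation) gets lateral Gaussian error of sd
#' `margin_noise_sd`, also fixed per rater and scan. With probability
#' `confusion_prob` a session commits a gross boundary confusion (e.g.
#' segmenting the vitreous interface instead of the ILM), offsetting the
#' whole ILM by `confusion_offset`.
#'
#' @param rater_id identifier string.
#' @param axial_noise_sd rater-level axial placement error sd, um.
#' @param session_noise_sd per-session axial error sd, um.
#' @param control_point_spacing lateral spacing of placed control points,
#'   um.
#' @param margin_noise_sd lateral sd of BM medial-margin placement, um.
#' @param confusion_prob per-session probability of a gross ILM confusion.
#' @param confusion_offset axial offset applied on a confusion event, um.
#' @param noise_corr_length correlation length of the placement error
#'   process, um.
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(rater_id, axial_noise_sd = 8, session_noise_sd = 2,
                        control_point_spacing = 200, margin_noise_sd = 50,
                        confusion_prob = 0, confusion_offset = 60,
                        noise_corr_length = 500) {
  if (axial_noise_sd < 0 || session_noise_sd < 0 || margin_noise_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (confusion_prob < 0 || confusion_prob > 1)
    stop("'confusion_prob' must lie in [0, 1]")
  if (control_point_spacing <= 0 || noise_corr_length <= 0)
    stop("'control_point_spacing' and 'noise_corr_length' must be positive")
  structure(list(rater_id = as.character(rater_id),
                 axial_noise_sd = axial_noise_sd,
                 session_noise_sd = session_noise_sd,
                 control_point_spacing = control_point_spacing,
                 margin_noise_sd = margin_noise_sd,
                 confusion_prob = confusion_prob,
                 confusion_offset = confusion_offset,
                 noise_corr_length = noise_corr_length),
            class = "rater_model")
}

#' Simulated OCT device
#'
#' Pixel grid, reported scaling, and error structure of one acquisition
#' device. `systematic_axial_offset` shifts every structure deeper or
#' shallower (a zero-reference difference); because the area integral is
#' invariant to a common axial shift of both boundaries, inter-device
#' *area* disagreement is instead driven by calibration error in the
#' reported scaling factors: the device's sidecar declares
#' `axial_scale`/`lateral_scale`, but the true pixel pitch differs by the
#' factors `axial_scale_error`/`lateral_scale_error`, so every measured
#' length (and hence the area, multiplicatively in both factors) is
#' mis-scaled.
#'
#' @param device_id identifier string.
#' @param axial_scale,lateral_scale scales declared in the metadata,
#'   um/pixel.
#' @param systematic_axial_offset common depth offset applied to all
#'   structures, um.
#' @param intensity_noise_sd speckle noise sd on rendered intensities
#'   (arbitrary units in \[0, 1\]).
#' @param axial_scale_error,lateral_scale_error multiplicative calibration
#'   error of the declared scales (1 = perfectly calibrated).
#' @param n_rows,n_cols rendered image size in pixels.
#' @return An object of class `device_model`.
#' @export
device_model <- function(device_id, axial_scale = 3.87, lateral_scale = 11.3,
                         systematic_axial_offset = 0,
                         intensity_noise_sd = 0.02,
                         axial_scale_error = 1, lateral_scale_error = 1,
                         n_rows = 496, n_cols = 512) {
  if (axial_scale <= 0 || lateral_scale <= 0)
    stop("declared scales must be positive")
  if (axial_scale_error <= 0 || lateral_scale_error <= 0)
    stop("scale error factors must be positive")
  structure(list(device_id = as.character(device_id),
                 axial_scale = axial_scale, lateral_scale = lateral_scale,
                 systematic_axial_offset = systematic_axial_offset,
                 intensity_noise_sd = intensity_noise_sd,
                 axial_scale_error = axial_scale_error,
                 lateral_scale_error = lateral_scale_error,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "device_model")
}

# Deterministic sub-seed derivation: every entity in a study draws its
# randomness from seeds chained off the single study seed.
sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1000003 + as.numeric(p)) %% 2147483629
  as.integer(s) + 1L
}

# Stationary Gaussian-process draw with squared-exponential correlation,
# using the current RNG state. Returns zeros when sd == 0.
gp_noise <- function(xs, sd, corr_length) {
  n <- length(xs)
  if (sd == 0 || n == 0L) return(numeric(n))
  d <- outer(xs, xs, "-")
  cc <- sd^2 * exp(-0.5 * (d / corr_length)^2)
  diag(cc) <- diag(cc) + sd^2 * 1e-8  # nugget for Cholesky stability
  drop(t(chol(cc)) %*% stats::rnorm(n))
}

#' Simulate a rater segmenting one scan
#'
#' Places control points every `control_point_spacing` um on the phantom's
#' ground-truth boundaries, perturbed by the rater noise model (see
#' [rater_model()]), and returns the resulting [scan_segmentation] in the
#' scan's pixel coordinates. Deterministic given the seeds: `rater_seed`
#' governs the rater-level components (placement-error process and margin
#' choice, shared between sessions of the same rater), `seed` the
#' session-level components.
#'
#' @param spec the [phantom_spec] describing the truth as it appears on
#'   this scan's coordinate frame (see [simulate_device()]).
#' @param scan the rendered [bscan].
#' @param model a [rater_model].
#' @param seed integer session seed.
#' @param rater_seed integer rater-level seed; defaults to `seed`.
#' @return A [scan_segmentation].
#' @export
simulate_rater <- function(spec, scan, model, seed, rater_seed = seed) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scan, "bscan"),
            inherits(model, "rater_model"))
  W <- scan_width_um(scan)
  sp <- model$control_point_spacing
  if (sp > W) stop("control-point spacing exceeds the scan width")
  # rater-level draws (shared across this rater's sessions)
  set.seed(rater_seed)
  m_l <- stats::rnorm(1, 0, model$margin_noise_sd)
  m_r <- stats::rnorm(1, 0, model$margin_noise_sd)
  xl <- spec$center_x - spec$bm_gap_half_width + m_l
  xr <- spec$center_x + spec$bm_gap_half_width + m_r
  xl <- min(max(xl, 2 * sp), spec$center_x - sp / 2)
  xr <- max(min(xr, W - 2 * sp), spec$center_x + sp / 2)
  xs_ilm <- um_grid(0, W, sp)
  xs_bml <- um_grid(0, xl, sp)
  xs_bmr <- um_grid(xr, W, sp)
  r_ilm <- gp_noise(xs_ilm, model$axial_noise_sd, model$noise_corr_length)
  r_bml <- gp_noise(xs_bml, model$axial_noise_sd, model$noise_corr_length)
  r_bmr <- gp_noise(xs_bmr, model$axial_noise_sd, model$noise_corr_length)
  # session-level draws
  set.seed(seed)
  s_ilm <- gp_noise(xs_ilm, model$session_noise_sd, model$noise_corr_length)
  s_bml <- gp_noise(xs_bml, model$session_noise_sd, model$noise_corr_length)
  s_bmr <- gp_noise(xs_bmr, model$session_noise_sd, model$noise_corr_length)
  confused <- model$confusion_prob > 0 &&
    stats::runif(1) < model$confusion_prob
  conf <- if (confused) model$confusion_offset else 0
  y_ilm <- phantom_truth(spec, xs_ilm)$y_ilm + r_ilm + s_ilm + conf
  y_bml <- rep(spec$bm_depth, length(xs_bml)) + r_bml + s_bml
  y_bmr <- rep(spec$bm_depth, length(xs_bmr)) + r_bmr + s_bmr
  to_px <- function(x, y) {
    cbind(col = x / scan$lateral_scale,
          row = pmin(pmax(y / scan$axial_scale, 0),
                     nrow(scan$pixels) - 1L))
  }
  scan_segmentation(
    scan_id = scan$scan_id, rater_id = model$rater_id,
    session_id = as.character(seed),
    ilm = boundary_segment("ILM", to_px(xs_ilm, y_ilm)),
    bm_left = boundary_segment("BM_left", to_px(xs_bml, y_bml)),
    bm_right = boundary_segment("BM_right", to_px(xs_bmr, y_bmr)))
}

#' Render a phantom on a simulated device
#'
#' Renders the phantom as an intensity image on the device's pixel grid
#' (dark background, bright bands at the boundary depths, no BM band in the
#' shadowed sub-nerve gap, Gaussian speckle noise) and returns both the
#' [bscan] and the *apparent* [phantom_spec]: the ground truth re-expressed
#' in the coordinate frame a user of the device's declared scaling factors
#' would reconstruct. The systematic axial offset shifts all depths; scale
#' calibration errors stretch the apparent axial and lateral coordinates by
#' their factors, which is what makes measured areas device-dependent.
#'
#' @param spec the true [phantom_spec] (physical um).
#' @param model a [device_model].
#' @param seed integer seed for the speckle noise.
#' @param scan_id,subject_id,eye,protocol metadata for the rendered scan.
#' @return List with components `scan` (a [bscan]) and `apparent_spec` (a
#'   [phantom_spec] covering exactly the rendered field of view).
#' @export
simulate_device <- function(spec, model, seed, scan_id = "scan",
                            subject_id = "subject", eye = "OD",
                            protocol = "radial") {
  stopifnot(inherits(spec, "phantom_spec"), inherits(model, "device_model"))
  e_a <- model$axial_scale_error; e_l <- model$lateral_scale_error
  fov_app <- (model$n_cols - 1L) * model$lateral_scale
  fov_true <- fov_app / e_l
  if (fov_true < 2 * spec$scan_half_width - 1e-9)
    stop("phantom is wider than the device field of view")
  off <- model$systematic_axial_offset
  apparent <- phantom_spec(
    baseline_ilm_depth = (spec$baseline_ilm_depth + off) * e_a,
    bump_amplitude = spec$bump_amplitude * e_a,
    bump_sigma = spec$bump_sigma * e_l,
    bm_depth = (spec$bm_depth + off) * e_a,
    bm_gap_half_width = spec$bm_gap_half_width * e_l,
    scan_half_width = fov_app / 2,
    center_x = fov_app / 2)
  # render in apparent coordinates: column j sits at x = j * lateral_scale
  xs <- (seq_len(model$n_cols) - 1L) * model$lateral_scale
  tr <- phantom_truth(apparent, xs)
  ilm_row <- tr$y_ilm / model$axial_scale
  bm_row <- tr$y_bm / model$axial_scale
  rows <- seq_len(model$n_rows) - 1L
  band <- function(center_row) {
    ok <- !is.na(center_row)
    m <- matrix(0, model$n_rows, model$n_cols)
    if (any(ok))
      m[, ok] <- 0.7 * exp(-(outer(rows, center_row[ok], "-"))^2 / (2 * 2^2))
    m
  }
  img <- 0.08 + band(ilm_row) + band(bm_row)
  # faint tissue between the boundaries
  interior <- outer(rows, ilm_row, ">") & outer(rows, bm_row2 <- ifelse(
    is.na(bm_row), apparent$bm_depth / model$axial_scale, bm_row), "<")
  img[interior] <- img[interior] + 0.12
  set.seed(seed)
  img <- img + stats::rnorm(length(img), 0, model$intensity_noise_sd)
  img <- pmin(pmax(img, 0), 1)
  scan <- bscan(img, axial_scale = model$axial_scale,
                lateral_scale = model$lateral_scale, scan_id = scan_id,
                subject_id = subject_id, eye = eye,
                device = model$device_id, protocol = protocol)
  list(scan = scan, apparent_spec = apparent)
}

#' Default phantom set: six swollen and four non-swollen nerve heads
#'
#' The default study population mirrors a small papilledema cohort: four
#' non-swollen eyes (flat ILM, varying retinal thickness) and six swollen
#' eyes with increasing elevation, calibrated so the ground-truth areas in
#' the 5.7 mm window span roughly 1.6 to 3.3 mm^2.
#'
#' @return Named list of ten [phantom_spec]s (`eye01` ... `eye10`);
#'   `eye01`-`eye04` non-swollen, the rest swollen.
#' @export
default_phantom_set <- function() {
  base <- 700
  par <- list(  # (bm - ilm depth gap, bump amplitude, bump sigma)
    c(285, 0, 700), c(300, 0, 700), c(315, 0, 700), c(330, 0, 700),
    c(300, 200, 700), c(300, 300, 750), c(310, 380, 800),
    c(310, 480, 800), c(320, 560, 850), c(320, 650, 900))
  out <- lapply(seq_along(par), function(i) {
    p <- par[[i]]
    phantom_spec(baseline_ilm_depth = base, bump_amplitude = p[2],
                 bump_sigma = p[3], bm_depth = base + p[1],
                 bm_gap_half_width = if (p[2] > 0) 600 else 400,
                 scan_half_width = 2850)
  })
  names(out) <- sprintf("eye%02d", seq_along(out))
  out
}

#' Default rater panel
#'
#' Three raters with identical noise structure: rater-level placement error
#' 8 um, session-level error 2 um (so repeat sessions of one rater agree
#' much more closely than two raters do), 200 um control-point spacing,
#' 50 um lateral sd on the BM medial-margin choice, no gross-confusion
#' events (enable `confusion_prob` explicitly to study outlier flagging).
#'
#' @return Named list of three [rater_model]s (`R1`, `R2`, `R3`).
#' @export
default_raters <- function() {
  out <- lapply(c("R1", "R2", "R3"), rater_model)
  names(out) <- c("R1", "R2", "R3")
  out
}

#' Default device panel
#'
#' Three devices with distinct pixel grids and declared scalings, small
#' systematic axial offsets, and +/-2% scale-calibration errors (applied to
#' both axes with a consistent sign per device). The calibration errors --
#' not the axial offsets, which cancel in the area integral -- are what
#' drive inter-device area disagreement, and at +/-2% they dominate the
#' rater-level noise.
#'
#' @return Named list of three [device_model]s.
#' @export
default_devices <- function() {
  out <- list(
    device_model("devA", axial_scale = 3.87, lateral_scale = 11.3,
                 n_rows = 496, n_cols = 512),
    device_model("devB", axial_scale = 3.10, lateral_scale = 11.25,
                 n_rows = 640, n_cols = 512,
                 systematic_axial_offset = 20,
                 axial_scale_error = 0.98, lateral_scale_error = 0.98),
    device_model("devC", axial_scale = 4.30, lateral_scale = 11.4,
                 n_rows = 448, n_cols = 516,
                 systematic_axial_offset = -15,
                 axial_scale_error = 1.02, lateral_scale_error = 1.02))
  names(out) <- vapply(out, `[[`, "", "device_id")
  out
}

#' Generate a complete synthetic reliability study
#'
#' Writes a full factorial study to disk in the interchange formats: every
#' phantom eye scanned on every device, segmented by every rater, with the
#' first rater contributing a repeat session. A manifest CSV keys every
#' file and carries the ground-truth area of each scan (in that device's
#' apparent coordinates). All randomness chains off the single study seed
#' through deterministic per-entity sub-seeds, so the same seed reproduces
#' the study byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param phantoms named list of [phantom_spec]s; default
#'   [default_phantom_set()].
#' @param devices named list of [device_model]s; default
#'   [default_devices()].
#' @param raters named list of [rater_model]s; default [default_raters()].
#' @param sessions number of sessions for the first rater (others do one).
#' @param seed study-level integer seed.
#' @param protocol protocol tag recorded on every scan.
#' @return The manifest as a data frame (invisibly); written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_study <- function(out_dir, phantoms = default_phantom_set(),
                           devices = default_devices(),
                           raters = default_raters(), sessions = 2,
                           seed = 1, protocol = "radial") {
  if (!length(devices) || !length(raters))
    stop("need at least one device and one rater")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(phantoms)))
    names(phantoms) <- sprintf("eye%02d", seq_along(phantoms))
  rows <- list()
  for (i in seq_along(phantoms)) {
    eye_id <- names(phantoms)[i]
    eye <- c("OD", "OS")[(i - 1L) %% 2L + 1L]
    for (j in seq_along(devices)) {
      dev <- devices[[j]]
      scan_id <- sprintf("%s_%s", eye_id, dev$device_id)
      sim <- simulate_device(phantoms[[i]], dev,
                             seed = sub_seed(seed, 1, i, j),
                             scan_id = scan_id, subject_id = eye_id,
                             eye = eye, protocol = protocol)
      scan_file <- file.path("scans", paste0(scan_id, ".tif"))
      write_bscan(sim$scan, file.path(out_dir, scan_file))
      truth_area <- analytic_area(sim$apparent_spec, 2.85)
      for (r in seq_along(raters)) {
        n_sess <- if (r == 1L) sessions else 1L
        rseed <- sub_seed(seed, 2, i, j, r)
        for (s in seq_len(n_sess)) {
          sseed <- sub_seed(seed, 3, i, j, r, s)
          seg <- simulate_rater(sim$apparent_spec, sim$scan, raters[[r]],
                                seed = sseed, rater_seed = rseed)
          seg$session_id <- sprintf("s%d", s)
          seg_file <- file.path(
            "segmentations",
            sprintf("%s_%s_s%d.json", scan_id, raters[[r]]$rater_id, s))
          save_segmentation(seg, file.path(out_dir, seg_file))
          rows[[length(rows) + 1L]] <- data.frame(
            scan_id = scan_id, subject_id = eye_id, eye = eye,
            device = dev$device_id, protocol = protocol,
            rater_id = raters[[r]]$rater_id, session_id = sprintf("s%d", s),
            scan_file = scan_file, seg_file = seg_file, quality = "ok",
            truth_area_mm2 = truth_area, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
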