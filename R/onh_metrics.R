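#' Bridge Bruch's membrane beneath the optic nerve head
#'
#' Under a swollen nerve the medial margins of Bruch's membrane are
#' shadowed, so raters delineate only the nasal and temporal wings. A
#' continuous BM boundary is recovered by keeping the fitted curve on each
#' wing and interpolating an exact straight line across the gap between the
#' medial margins (the last control point of the left wing and the first of
#' the right). The bridged curve is continuous at both junctions by
#' construction.
#'
#' @param seg a [scan_segmentation].
#' @param scan the owning [bscan].
#' @param step grid step in micrometres for the returned sampling.
#' @return A `sampled_boundary` over the union support of both wings.
#' @export
bridge_bm <- function(seg, scan, step = 5) {
  stopifnot(inherits(seg, "scan_segmentation"), inherits(scan, "bscan"))
  f <- bridged_bm_fun(seg, scan)
  lo <- min(seg$bm_left$points[, 1L]) * scan$lateral_scale
  hi <- max(seg$bm_right$points[, 1L]) * scan$lateral_scale
  xs <- um_grid(lo, hi, step)
  structure(list(xs = xs, ys = f(xs)), class = "sampled_boundary")
}

# Continuous bridged-BM evaluator in micrometre coordinates: fitted wing
# curves outside the gap, straight chord between the medial margins inside.
# A zero-width gap degenerates to direct concatenation of the wings.
bridged_bm_fun <- function(seg, scan) {
  ls <- scan$lateral_scale; as_ <- scan$axial_scale
  pl <- seg$bm_left$points; pr <- seg$bm_right$points
  fl <- hermite_fun(pl[, 1L] * ls, pl[, 2L] * as_)
  fr <- hermite_fun(pr[, 1L] * ls, pr[, 2L] * as_)
  xl <- pl[nrow(pl), 1L] * ls; yl <- pl[nrow(pl), 2L] * as_
  xr <- pr[1L, 1L] * ls;       yr <- pr[1L, 2L] * as_
  lo_l <- pl[1L, 1L] * ls; hi_r <- pr[nrow(pr), 1L] * ls
  function(x) {
    if (any(x < lo_l - 1e-9) || any(x > hi_r + 1e-9))
      stop("x outside the bridged BM support")
    y <- numeric(length(x))
    left <- x <= xl; right <- x >= xr; gap <- !left & !right
    y[left] <- fl(x[left])
    y[right] <- fr(x[right])
    if (any(gap))
      y[gap] <- yl + (yr - yl) * (x[gap] - xl) / (xr - xl)
    y
  }
}

# ILM evaluator in micrometre coordinates.
ilm_fun <- function(seg, scan) {
  p <- seg$ilm$points
  ls <- scan$lateral_scale; as_ <- scan$axial_scale
  f <- hermite_fun(p[, 1L] * ls, p[, 2L] * as_)
  lo <- p[1L, 1L] * ls; hi <- p[nrow(p), 1L] * ls
  function(x) {
    if (any(x < lo - 1e-9) || any(x > hi + 1e-9))
      stop("x outside the ILM support")
    f(x)
  }
}

trapz_um <- function(xs, ys)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)

#' Optic nerve head cross-sectional area
#'
#' The core morphometric score: the area between the ILM and the bridged BM
#' boundary, integrated over a window truncated to `half_width` mm on
#' either side of the scan centre (default 2.85 mm, a 5.7 mm diameter
#' window). The integrand `y_BM(x) - y_ILM(x)` is kept signed: if the
#' delineated boundaries cross, the crossing region reduces the area and a
#' warning is raised, rather than being silently clipped.
#'
#' @param seg a [scan_segmentation].
#' @param scan the owning [bscan].
#' @param half_width half-width of the integration window in millimetres.
#' @param step integration grid step in micrometres.
#' @param center_x window centre in micrometres; defaults to the lateral
#'   midpoint of the scan (acquisition centres the scan on the nerve head).
#' @return An `area_result`: list with `scan_id`, `rater_id`, `session_id`,
#'   `area_mm2`, `window_half_width_mm`, `center_x_um`.
#' @examples
#' # flat ILM at 100 um over flat BM at 400 um -> 0.3 mm x 5.7 mm = 1.71 mm^2
#' @export
cross_sectional_area <- function(seg, scan, half_width = 2.85, step = 5,
                                 center_x = NULL) {
  stopifnot(inherits(seg, "scan_segmentation"), inherits(scan, "bscan"))
  if (!is.numeric(half_width) || half_width <= 0)
    stop("'half_width' must be positive (mm)")
  if (is.null(center_x)) center_x <- scan_width_um(scan) / 2
  hw_um <- half_width * 1000
  lo <- center_x - hw_um; hi <- center_x + hw_um
  ls <- scan$lateral_scale
  ilm_lo <- min(seg$ilm$points[, 1L]) * ls
  ilm_hi <- max(seg$ilm$points[, 1L]) * ls
  bm_lo <- min(seg$bm_left$points[, 1L]) * ls
  bm_hi <- max(seg$bm_right$points[, 1L]) * ls
  if (lo < max(ilm_lo, bm_lo) - 1e-9 || hi > min(ilm_hi, bm_hi) + 1e-9)
    stop("integration window exceeds the lateral support of ILM or BM")
  xs <- um_grid(lo, hi, step)
  gap <- bridged_bm_fun(seg, scan)(xs) - ilm_fun(seg, scan)(xs)
  if (any(gap < -1e-6))  # tolerate float noise on coincident boundaries
    warning("ILM lies below BM on part of the window; ",
            "signed integrand reduces the area")
  structure(list(scan_id = seg$scan_id, rater_id = seg$rater_id,
                 session_id = seg$session_id,
                 area_mm2 = trapz_um(xs, gap) * 1e-6,
                 window_half_width_mm = half_width,
                 center_x_um = center_x),
            class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("<area_result> scan %s rater %s session %s: %.4f mm^2 (%.3g mm window)\n",
              x$scan_id, x$rater_id, x$session_id, x$area_mm2,
              2 * x$window_half_width_mm))
  invisible(x)
}

#' Mean absolute axial segmentation difference between two delineations
#'
#' Quantifies rater disagreement for one boundary: the absolute difference
#' in axial location between two segmentations of the same scan, evaluated
#' at each lateral position on a uniform grid over the intersection of the
#' two lateral supports, and averaged across the B-scan. For `"BM"` the
#' comparison uses the bridged continuous boundary, so inconsistent
#' identification of the medial margins propagates into the interpolated
#' sub-nerve line exactly as it does in the area score. Absolute (not
#' signed) differences are averaged, so the result is a per-scan
#' disagreement magnitude.
#'
#' @param a,b two [scan_segmentation]s of the same scan.
#' @param label `"ILM"` or `"BM"`.
#' @param scan the shared [bscan].
#' @param step evaluation grid step in micrometres.
#' @param comparison tag recorded in the result: `"intra_rater"`,
#'   `"inter_rater"`, or `"inter_device"`.
#' @return A `difference_pair`: list with `scan_id`, `segment_label`,
#'   `comparison`, `mean_abs_diff_um`, `mean_abs_diff_px`, and the ids of
#'   both contributors.
#' @export
segmentation_difference <- function(a, b, label = c("ILM", "BM"), scan,
                                    step = 5,
                                    comparison = c("inter_rater",
                                                   "intra_rater",
                                                   "inter_device")) {
  stopifnot(inherits(a, "scan_segmentation"),
            inherits(b, "scan_segmentation"), inherits(scan, "bscan"))
  label <- match.arg(label)
  comparison <- match.arg(comparison)
  if (a$scan_id != b$scan_id)
    stop("both segmentations must refer to the same scan_id")
  ls <- scan$lateral_scale
  if (label == "ILM") {
    fa <- ilm_fun(a, scan); fb <- ilm_fun(b, scan)
    lo <- max(min(a$ilm$points[, 1L]), min(b$ilm$points[, 1L])) * ls
    hi <- min(max(a$ilm$points[, 1L]), max(b$ilm$points[, 1L])) * ls
  } else {
    fa <- bridged_bm_fun(a, scan); fb <- bridged_bm_fun(b, scan)
    lo <- max(min(a$bm_left$points[, 1L]), min(b$bm_left$points[, 1L])) * ls
    hi <- min(max(a$bm_right$points[, 1L]),
              max(b$bm_right$points[, 1L])) * ls
  }
  if (hi <= lo) stop("the two lateral supports do not intersect")
  xs <- um_grid(lo, hi, step)
  d_um <- mean(abs(fa(xs) - fb(xs)))
  structure(list(scan_id = a$scan_id, segment_label = label,
                 comparison = comparison,
                 id_a = paste(a$rater_id, a$session_id, sep = "/"),
                 id_b = paste(b$rater_id, b$session_id, sep = "/"),
                 mean_abs_diff_um = d_um,
                 mean_abs_diff_px = d_um / scan$axial_scale),
            class = "difference_pair")
}

#' @export
print.difference_pair <- function(x, ...) {
  cat(sprintf("<difference_pair> scan %s %s (%s): %.2f um (%.2f px) [%s vs %s]\n",
              x$scan_id, x$segment_label, x$comparison, x$mean_abs_diff_um,
              x$mean_abs_diff_px, x$id_a, x$id_b))
  invisible(x)
}
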