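#' Control-point boundary segment
#'
#' The semi-manual segmentation workflow represents each retinal boundary
#' (the internal limiting membrane, or one wing of Bruch's membrane) as an
#' ordered list of rater-placed control points in pixel coordinates, with a
#' shape-preserving curve fitted through them. Control points may have
#' fractional pixel coordinates (cursor placement is sub-pixel) but must
#' have strictly increasing lateral positions: a boundary is a single-valued
#' curve in the lateral coordinate, and two points at the same abscissa are
#' an error, never a silent merge.
#'
#' @param label one of `"ILM"`, `"BM_left"`, `"BM_right"`.
#' @param points two-column numeric matrix (col, row) of control points in
#'   0-based pixel coordinates, or a list of length-2 vectors.
#' @return An object of class `boundary_segment`.
#' @examples
#' boundary_segment("ILM", cbind(c(0, 50, 100), c(120, 80, 120)))
#' @export
boundary_segment <- function(label, points) {
  label <- match.arg(label, c("ILM", "BM_left", "BM_right"))
  if (is.list(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (ncol(points) != 2L || !is.numeric(points))
    stop("'points' must be a two-column numeric (col, row) matrix")
  if (nrow(points) < 2L)
    stop("a boundary segment needs at least 2 control points")
  if (anyNA(points)) stop("control points must not contain NA")
  if (any(diff(points[, 1L]) <= 0))
    stop("control point columns must be strictly increasing")
  dimnames(points) <- list(NULL, c("col", "row"))
  structure(list(label = label, points = points), class = "boundary_segment")
}

#' @export
print.boundary_segment <- function(x, ...) {
  cat(sprintf("<boundary_segment> %s: %d control points, cols [%g, %g]\n",
              x$label, nrow(x$points), min(x$points[, 1L]),
              max(x$points[, 1L])))
  invisible(x)
}

#' One rater's delineation of a scan
#'
#' Bundles a rater's single-session segmentation of one B-scan: the ILM and
#' the two Bruch's-membrane wings flanking the optic nerve canal. The wings
#' must not overlap laterally (the gap between their medial endpoints is the
#' sub-nerve region later bridged by a straight line), and the ILM must
#' cover the lateral support of both wings.
#'
#' @param scan_id,rater_id,session_id identifier strings.
#' @param ilm,bm_left,bm_right [boundary_segment] objects with the matching
#'   labels.
#' @return An object of class `scan_segmentation`.
#' @export
scan_segmentation <- function(scan_id, rater_id, session_id,
                              ilm, bm_left, bm_right) {
  stopifnot(inherits(ilm, "boundary_segment"),
            inherits(bm_left, "boundary_segment"),
            inherits(bm_right, "boundary_segment"))
  if (ilm$label != "ILM" || bm_left$label != "BM_left" ||
      bm_right$label != "BM_right")
    stop("segments must carry labels ILM, BM_left, BM_right respectively")
  if (max(bm_left$points[, 1L]) >= min(bm_right$points[, 1L]))
    stop("BM wings overlap: bm_left must end strictly before bm_right starts")
  ilm_lo <- min(ilm$points[, 1L]); ilm_hi <- max(ilm$points[, 1L])
  if (ilm_lo > min(bm_left$points[, 1L]) || ilm_hi < max(bm_right$points[, 1L]))
    stop("ILM lateral support must cover the union of both BM supports")
  structure(list(scan_id = as.character(scan_id),
                 rater_id = as.character(rater_id),
                 session_id = as.character(session_id),
                 ilm = ilm, bm_left = bm_left, bm_right = bm_right),
            class = "scan_segmentation")
}

#' @export
print.scan_segmentation <- function(x, ...) {
  cat(sprintf("<scan_segmentation> scan %s, rater %s, session %s\n",
              x$scan_id, x$rater_id, x$session_id))
  cat(sprintf("  ILM %d pts; BM_left %d pts (to col %g); BM_right %d pts (from col %g)\n",
              nrow(x$ilm$points), nrow(x$bm_left$points),
              max(x$bm_left$points[, 1L]), nrow(x$bm_right$points),
              min(x$bm_right$points[, 1L])))
  invisible(x)
}

#' Fit the boundary curve through control points
#'
#' Interpolates a segment's control points with a shape-preserving monotone
#' piecewise-cubic Hermite interpolant (Fritsch--Carlson). The fitted curve
#' passes through every control point exactly, is continuous, and between
#' consecutive control points with monotone ordinates never overshoots the
#' local data range -- the behaviour a rater-adjusted anatomical boundary
#' requires, which an unconstrained cubic spline (prone to ringing between
#' sparse points) does not guarantee.
#'
#' @param segment a [boundary_segment].
#' @param xs lateral evaluation positions in pixel columns; must lie within
#'   the control-point span.
#' @return Axial values (pixel rows) at `xs`.
#' @examples
#' seg <- boundary_segment("ILM", cbind(c(0, 5, 10), c(10, 20, 30)))
#' fit_boundary(seg, c(2.5, 7.5))  # 15, 25
#' @export
fit_boundary <- function(segment, xs) {
  stopifnot(inherits(segment, "boundary_segment"))
  p <- segment$points
  if (any(xs < p[1L, 1L]) || any(xs > p[nrow(p), 1L]))
    stop("'xs' outside the control-point span [",
         p[1L, 1L], ", ", p[nrow(p), 1L], "]")
  hermite_fun(p[, 1L], p[, 2L])(xs)
}

# Fritsch--Carlson shape-preserving node slopes: zero at every local
# extremum of the data (so the cubic cannot overshoot the neighbouring
# ordinates there), secant-mean elsewhere, then limited to the circle
# alpha^2 + beta^2 <= 9 which is sufficient for monotonicity on each
# monotone data interval.
fc_slopes <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  m <- numeric(n)
  m[1L] <- delta[1L]
  m[n] <- delta[n - 1L]
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      m[i] <- if (delta[i - 1L] * delta[i] <= 0) 0
      else (delta[i - 1L] + delta[i]) / 2
    }
  }
  for (i in seq_len(n - 1L)) {
    if (delta[i] == 0) {
      m[i] <- 0; m[i + 1L] <- 0
    } else {
      a <- m[i] / delta[i]; b <- m[i + 1L] / delta[i]
      r2 <- a^2 + b^2
      if (r2 > 9) {
        tau <- 3 / sqrt(r2)
        m[i] <- tau * a * delta[i]
        m[i + 1L] <- tau * b * delta[i]
      }
    }
  }
  m
}

# Piecewise cubic Hermite evaluator through (x, y) with FC slopes.
hermite_fun <- function(x, y) {
  m <- fc_slopes(x, y)
  force(x); force(y)
  function(xs) {
    i <- findInterval(xs, x, rightmost.closed = TRUE)
    i[i < 1L] <- 1L
    i[i > length(x) - 1L] <- length(x) - 1L
    h <- x[i + 1L] - x[i]
    t <- (xs - x[i]) / h
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1L] + h11 * h * m[i + 1L]
  }
}

#' Resample a fitted boundary on a uniform micrometre grid
#'
#' Evaluates the fitted curve on a uniform lateral grid (in micrometres)
#' spanning the segment's support and converts axial values to micrometres
#' using the scan's scaling factors. The realised grid step is the largest
#' value not exceeding `step` that divides the support evenly, so both
#' endpoints are always included.
#'
#' @param segment a [boundary_segment].
#' @param scan the owning [bscan] (supplies the um-per-pixel scales).
#' @param step requested grid step in micrometres (> 0).
#' @return A `sampled_boundary`: list with `xs` (lateral um, uniform,
#'   strictly increasing) and `ys` (axial depth um).
#' @export
resample_boundary <- function(segment, scan, step = 5) {
  stopifnot(inherits(segment, "boundary_segment"), inherits(scan, "bscan"))
  if (!is.numeric(step) || step <= 0) stop("'step' must be positive")
  p <- segment$points
  lo <- p[1L, 1L] * scan$lateral_scale
  hi <- p[nrow(p), 1L] * scan$lateral_scale
  if (step > hi - lo)
    stop("'step' exceeds the lateral support width (", hi - lo, " um)")
  xs <- um_grid(lo, hi, step)
  ys <- fit_boundary(segment, xs / scan$lateral_scale) * scan$axial_scale
  structure(list(xs = xs, ys = ys), class = "sampled_boundary")
}

# Uniform grid on [lo, hi] with step <= requested, endpoints exact.
um_grid <- function(lo, hi, step) {
  n <- max(1L, as.integer(ceiling((hi - lo) / step - 1e-9)))
  seq(lo, hi, length.out = n + 1L)
}

#' Edit a control point
#'
#' Reproduces the rater interaction loop: points can be added, removed, or
#' moved, and the curve is refitted from the updated set. Edits that would
#' break the segment invariants (fewer than 2 points, duplicated or
#' non-increasing columns) are errors.
#'
#' @param segment a [boundary_segment].
#' @param action `"add"`, `"remove"`, or `"move"`.
#' @param point for `"add"` and `"move"`, the (col, row) pair to insert or
#'   the new location.
#' @param at for `"remove"` and `"move"`, the column of the existing control
#'   point being edited (matched exactly).
#' @return The edited [boundary_segment].
#' @export
edit_control_point <- function(segment, action = c("add", "remove", "move"),
                               point = NULL, at = NULL) {
  stopifnot(inherits(segment, "boundary_segment"))
  action <- match.arg(action)
  p <- segment$points
  if (action %in% c("remove", "move")) {
    if (is.null(at)) stop("'at' (column of the existing point) is required")
    i <- which(p[, 1L] == at)
    if (length(i) != 1L) stop("no control point at col = ", at)
  }
  p <- switch(action,
    add = {
      if (is.null(point)) stop("'point' is required for add")
      if (any(p[, 1L] == point[1L]))
        stop("a control point already exists at col = ", point[1L])
      rbind(p, point)[order(c(p[, 1L], point[1L])), , drop = FALSE]
    },
    remove = {
      if (nrow(p) <= 2L) stop("removal would leave fewer than 2 points")
      p[-i, , drop = FALSE]
    },
    move = {
      if (is.null(point)) stop("'point' is required for move")
      p[i, ] <- point
      p[order(p[, 1L]), , drop = FALSE]
    })
  boundary_segment(segment$label, p)
}

#' Save / load a scan segmentation as JSON
#'
#' Versioned JSON interchange for segmentations:
#' `{schema, scan_id, rater_id, session_id, segments: [{label, points:
#' [[col, row], ...]}, ...]}`. Loading validates every segment invariant
#' (ordering, wing overlap, ILM coverage), so a hand-edited file that
#' violates them is rejected.
#'
#' @param seg a [scan_segmentation].
#' @param path JSON file path.
#' @return `save_segmentation` returns `path` invisibly;
#'   `load_segmentation` returns the [scan_segmentation].
#' @export
save_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "scan_segmentation"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  seg_block <- function(s)
    list(label = s$label,
         points = lapply(seq_len(nrow(s$points)),
                         function(i) as.numeric(s$points[i, ])))
  out <- list(schema = "onhrel-segmentation-v1",
              scan_id = seg$scan_id, rater_id = seg$rater_id,
              session_id = seg$session_id,
              segments = list(seg_block(seg$ilm), seg_block(seg$bm_left),
                              seg_block(seg$bm_right)))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_segmentation
#' @export
load_segmentation <- function(path) {
  if (!file.exists(path)) stop("segmentation file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  required <- c("scan_id", "rater_id", "session_id", "segments")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("segmentation JSON missing fields: ",
         paste(missing, collapse = ", "))
  segs <- lapply(raw$segments, function(s) {
    pts <- do.call(rbind, lapply(s$points, as.numeric))
    boundary_segment(s$label, pts)
  })
  labels <- vapply(segs, `[[`, "", "label")
  need <- c("ILM", "BM_left", "BM_right")
  if (!setequal(labels, need))
    stop("segmentation JSON must contain exactly ILM, BM_left, BM_right")
  scan_segmentation(raw$scan_id, raw$rater_id, raw$session_id,
                    ilm = segs[[match("ILM", labels)]],
                    bm_left = segs[[match("BM_left", labels)]],
                    bm_right = segs[[match("BM_right", labels)]])
}
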