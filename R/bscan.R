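#' B-scan container with physical scaling
#'
#' A `bscan` holds one cross-sectional OCT image (rows = axial depth,
#' columns = lateral position) together with the per-image scaling factors
#' that convert pixel indices to micrometres. All downstream geometry
#' (boundary fitting, bridging, areas, differences) works in micrometres and
#' depends on the image only through these scales, so the container is
#' device-agnostic.
#'
#' Intensities are stored on the 16-bit grayscale grid (multiples of
#' 1/65535 in \[0, 1\]); arbitrary numeric input is quantized on
#' construction so that writing and re-reading a scan is an exact identity.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\]; rows are axial
#'   (depth increases downward), columns lateral (left to right).
#' @param axial_scale axial scaling, micrometres per pixel (> 0).
#' @param lateral_scale lateral scaling, micrometres per pixel (> 0).
#' @param scan_id,subject_id opaque identifier strings.
#' @param eye laterality tag, `"OD"` or `"OS"`.
#' @param device device label string.
#' @param protocol scan protocol tag, `"line"` or `"radial"`.
#'
#' @return An object of class `bscan`.
#' @examples
#' sc <- bscan(matrix(0, 8, 16), axial_scale = 3.87, lateral_scale = 11.3)
#' scan_width_um(sc)
#' @export
bscan <- function(pixels, axial_scale, lateral_scale,
                  scan_id = "scan", subject_id = "subject",
                  eye = "OD", device = "device", protocol = "radial") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("'pixels' must have at least 2 rows and 2 columns")
  if (!is.numeric(axial_scale) || length(axial_scale) != 1L ||
      !is.finite(axial_scale) || axial_scale <= 0)
    stop("'axial_scale' must be a single positive number (um/pixel)")
  if (!is.numeric(lateral_scale) || length(lateral_scale) != 1L ||
      !is.finite(lateral_scale) || lateral_scale <= 0)
    stop("'lateral_scale' must be a single positive number (um/pixel)")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1] with no missing values")
  eye <- match.arg(eye, c("OD", "OS"))
  protocol <- match.arg(protocol, c("line", "radial"))
  pixels <- round(pixels * 65535) / 65535  # 16-bit grayscale grid
  structure(
    list(scan_id = as.character(scan_id),
         subject_id = as.character(subject_id),
         eye = eye, device = as.character(device), protocol = protocol,
         pixels = pixels,
         axial_scale = as.numeric(axial_scale),
         lateral_scale = as.numeric(lateral_scale)),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %s  (%s, %s eye, %s protocol)\n",
              x$scan_id, x$device, x$eye, x$protocol))
  cat(sprintf("  %d x %d px, axial %.4g um/px, lateral %.4g um/px (%.3g x %.3g mm)\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_scale, x$lateral_scale,
              (nrow(x$pixels) - 1L) * x$axial_scale / 1000,
              scan_width_um(x) / 1000))
  invisible(x)
}

#' Physical lateral width of a scan
#'
#' Width in micrometres between the centres of the first and last pixel
#' columns, i.e. `(ncol - 1) * lateral_scale`.
#'
#' @param scan a [bscan].
#' @return Width in micrometres.
#' @export
scan_width_um <- function(scan) {
  stopifnot(inherits(scan, "bscan"))
  (ncol(scan$pixels) - 1L) * scan$lateral_scale
}

#' Convert pixel indices to micrometre coordinates
#'
#' Pixel indices are 0-based with the physical origin at the centre of pixel
#' (0, 0); the axial coordinate increases downward (deeper into tissue) and
#' the lateral coordinate left to right. Indices may be fractional
#' (sub-pixel cursor placements).
#'
#' @param col,row 0-based pixel indices (vectors allowed, possibly
#'   fractional).
#' @param scan a [bscan] supplying the scaling factors.
#' @return A list with components `x` (lateral, um) and `y` (axial depth,
#'   um).
#' @examples
#' sc <- bscan(matrix(0, 200, 300), axial_scale = 3.87, lateral_scale = 11.3)
#' pixel_to_um(100, 0, sc)$x  # 1130
#' @export
pixel_to_um <- function(col, row, scan) {
  stopifnot(inherits(scan, "bscan"))
  if (any(col < 0) || any(col > ncol(scan$pixels) - 1L))
    stop("'col' out of range [0, ncol - 1]")
  if (any(row < 0) || any(row > nrow(scan$pixels) - 1L))
    stop("'row' out of range [0, nrow - 1]")
  list(x = col * scan$lateral_scale, y = row * scan$axial_scale)
}

#' Read a B-scan from its interchange files
#'
#' The interchange format is a 16-bit grayscale TIFF plus a JSON metadata
#' sidecar (`<path>.json`) carrying identifiers, protocol and the
#' micrometre-per-pixel scales. Scaling must always come from the sidecar;
#' a missing or non-positive scale is an error, never a default.
#'
#' @param path path to the TIFF image; the sidecar is `<path>.json`.
#' @return A [bscan].
#' @seealso [write_bscan()]
#' @export
read_bscan <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("metadata sidecar not found: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  required <- c("scan_id", "subject_id", "eye", "device", "protocol",
                "axial_scale_um", "lateral_scale_um", "rows", "cols")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("sidecar is missing fields: ", paste(missing, collapse = ", "))
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # tolerate replicated channels
  if (nrow(px) != meta$rows || ncol(px) != meta$cols)
    stop(sprintf("image is %d x %d but sidecar declares %d x %d",
                 nrow(px), ncol(px), meta$rows, meta$cols))
  bscan(px,
        axial_scale = meta$axial_scale_um,
        lateral_scale = meta$lateral_scale_um,
        scan_id = meta$scan_id, subject_id = meta$subject_id,
        eye = meta$eye, device = meta$device, protocol = meta$protocol)
}

#' Write a B-scan to the interchange format
#'
#' Writes a 16-bit grayscale TIFF and a JSON sidecar such that
#' [read_bscan()] reproduces every field exactly. Repeated writes of the
#' same scan yield byte-identical sidecars.
#'
#' @param scan a [bscan].
#' @param path output path for the TIFF image; the sidecar is written next
#'   to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(scan, path) {
  stopifnot(inherits(scan, "bscan"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch(tiff::writeTIFF(scan$pixels, path, bits.per.sample = 16L),
                 error = function(e) stop("cannot write image: ",
                                          conditionMessage(e)))
  meta <- list(schema = "onhrel-bscan-v1",
               scan_id = scan$scan_id, subject_id = scan$subject_id,
               eye = scan$eye, device = scan$device, protocol = scan$protocol,
               axial_scale_um = scan$axial_scale,
               lateral_scale_um = scan$lateral_scale,
               rows = nrow(scan$pixels), cols = ncol(scan$pixels))
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  writeLines(json, paste0(path, ".json"))
  invisible(path)
}
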