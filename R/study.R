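#' Validate a study manifest
#'
#' Checks a manifest CSV (or data frame) for the problems that would break
#' a reliability run: missing required columns, referenced files that do
#' not exist, duplicated (scan, rater, session) keys, and quality-flagged
#' scans (exclusion is manifest-driven: a `quality` value other than
#' `"ok"` marks a scan the acquisition deemed unusable).
#'
#' @param manifest path to a manifest CSV or a data frame; file paths are
#'   resolved relative to the manifest's directory.
#' @param base_dir base directory for relative paths (defaults to the
#'   manifest's directory, or `"."` for data-frame input).
#' @return Data frame of issues with columns `type` and `message`;
#'   zero rows when the manifest is clean.
#' @export
validate_manifest <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  issues <- list()
  add <- function(type, message)
    issues[[length(issues) + 1L]] <<- data.frame(type = type,
                                                 message = message)
  required <- c("scan_id", "subject_id", "device", "protocol", "rater_id",
                "session_id", "scan_file", "seg_file", "quality")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    add("missing_column", paste("manifest lacks columns:",
                                paste(missing_cols, collapse = ", ")))
    return(do.call(rbind, issues))
  }
  for (f in unique(c(manifest$scan_file, manifest$seg_file)))
    if (!file.exists(file.path(base_dir, f)))
      add("missing_file", paste("file not found:", f))
  key <- paste(manifest$scan_id, manifest$rater_id, manifest$session_id)
  for (k in unique(key[duplicated(key)]))
    add("duplicate_key", paste("duplicated (scan, rater, session):", k))
  for (i in which(manifest$quality != "ok"))
    add("quality_flag",
        sprintf("scan %s flagged '%s' and will be excluded",
                manifest$scan_id[i], manifest$quality[i]))
  if (length(issues)) do.call(rbind, issues)
  else data.frame(type = character(), message = character())
}

all_pairs <- function(v) {
  if (length(v) < 2L) return(NULL)
  utils::combn(v, 2L, simplify = FALSE)
}

#' Run the end-to-end reliability study
#'
#' Orchestrates the full measurement chain on a manifest of scans and
#' segmentations: computes the truncated ILM-to-BM cross-sectional area for
#' every segmentation; pairwise axial segmentation differences (ILM and
#' bridged BM) and absolute area differences within raters (repeat
#' sessions) and between raters; absolute area differences between devices;
#' limits of agreement with outlier flags for every difference stratum;
#' pooled two-way random absolute-agreement ICCs per comparison type; and
#' Bland--Altman summaries per measurer pair.
#'
#' All summaries are stratified by scan protocol and never pooled across
#' protocols, and device comparisons are computed for the radial protocol
#' only (line-scan positioning varies too much between devices for a
#' meaningful cross-device comparison). Scans whose manifest `quality`
#' field is not `"ok"` are excluded, and each exclusion is recorded in the
#' report log.
#'
#' @param manifest manifest CSV path or data frame (see
#'   [validate_manifest()]).
#' @param half_width area truncation half-width, mm.
#' @param step sampling step for boundary evaluation and integration, um.
#' @param comparisons subset of `"intra_rater"`, `"inter_rater"`,
#'   `"inter_device"` to compute.
#' @param out_dir if non-NULL, write `areas.csv`, `differences.csv`,
#'   `loa.csv`, `bland_altman.csv` and `icc.json` there.
#' @param base_dir base directory for relative manifest paths.
#' @return An object of class `onh_study`; see [print.onh_study()].
#' @export
run_study <- function(manifest, half_width = 2.85, step = 5,
                      comparisons = c("intra_rater", "inter_rater",
                                      "inter_device"),
                      out_dir = NULL, base_dir = NULL) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  issues <- validate_manifest(manifest, base_dir = base_dir)
  hard <- issues[issues$type %in% c("missing_column", "missing_file",
                                    "duplicate_key"), , drop = FALSE]
  if (nrow(hard))
    stop("manifest is not runnable:\n  ",
         paste(hard$message, collapse = "\n  "))
  log <- character()
  excl <- manifest$quality != "ok"
  if (any(excl)) {
    log <- sprintf("excluded scan %s (rater %s, session %s): quality '%s'",
                   manifest$scan_id[excl], manifest$rater_id[excl],
                   manifest$session_id[excl], manifest$quality[excl])
    manifest <- manifest[!excl, , drop = FALSE]
  }
  if (!nrow(manifest)) stop("no usable manifest rows remain")

  scans <- new.env(parent = emptyenv())
  get_scan <- function(f) {
    if (is.null(scans[[f]]))
      scans[[f]] <- read_bscan(file.path(base_dir, f))
    scans[[f]]
  }
  segs <- lapply(manifest$seg_file,
                 function(f) load_segmentation(file.path(base_dir, f)))

  areas <- manifest[c("scan_id", "subject_id", "device", "protocol",
                      "rater_id", "session_id")]
  areas$area_mm2 <- vapply(seq_len(nrow(manifest)), function(i) {
    cross_sectional_area(segs[[i]], get_scan(manifest$scan_file[i]),
                         half_width = half_width, step = step)$area_mm2
  }, 0)
  if ("truth_area_mm2" %in% names(manifest))
    areas$truth_area_mm2 <- manifest$truth_area_mm2

  diffs <- list()
  rec <- function(comparison, protocol, key, metric, id_a, id_b, value,
                  value_px = NA_real_, unit)
    diffs[[length(diffs) + 1L]] <<- data.frame(
      comparison = comparison, protocol = protocol, key = key,
      metric = metric, id_a = id_a, id_b = id_b, value = value,
      value_px = value_px, unit = unit, stringsAsFactors = FALSE)

  seg_pair <- function(i, j, comparison) {
    scan <- get_scan(manifest$scan_file[i])
    for (lab in c("ILM", "BM")) {
      d <- segmentation_difference(segs[[i]], segs[[j]], lab, scan,
                                   step = step, comparison = comparison)
      rec(comparison, manifest$protocol[i], manifest$scan_id[i], lab,
          d$id_a, d$id_b, d$mean_abs_diff_um, d$mean_abs_diff_px, "um")
    }
    rec(comparison, manifest$protocol[i], manifest$scan_id[i], "area",
        paste(manifest$rater_id[i], manifest$session_id[i], sep = "/"),
        paste(manifest$rater_id[j], manifest$session_id[j], sep = "/"),
        abs(areas$area_mm2[i] - areas$area_mm2[j]), unit = "mm2")
  }

  if ("intra_rater" %in% comparisons) {
    grp <- split(seq_len(nrow(manifest)),
                 paste(manifest$scan_id, manifest$rater_id))
    for (g in grp) {
      g <- g[order(manifest$session_id[g])]
      for (p in all_pairs(g)) seg_pair(p[1L], p[2L], "intra_rater")
    }
  }
  first_session <- function(idx) {
    # one row per rater: that rater's first session on the scan
    o <- idx[order(manifest$rater_id[idx], manifest$session_id[idx])]
    o[!duplicated(manifest$rater_id[o])]
  }
  if ("inter_rater" %in% comparisons) {
    for (g in split(seq_len(nrow(manifest)), manifest$scan_id)) {
      for (p in all_pairs(first_session(g)))
        seg_pair(p[1L], p[2L], "inter_rater")
    }
  }
  if ("inter_device" %in% comparisons) {
    rad <- which(manifest$protocol == "radial")
    grp <- split(rad, paste(manifest$subject_id[rad],
                            manifest$rater_id[rad]))
    for (g in grp) {
      g <- g[order(manifest$device[g], manifest$session_id[g])]
      g <- g[!duplicated(manifest$device[g])]  # first session per device
      g <- g[order(manifest$device[g])]
      for (p in all_pairs(g))
        rec("inter_device", "radial", manifest$subject_id[p[1L]], "area",
            manifest$device[p[1L]], manifest$device[p[2L]],
            abs(areas$area_mm2[p[1L]] - areas$area_mm2[p[2L]]),
            unit = "mm2")
    }
  }
  differences <- if (length(diffs)) do.call(rbind, diffs) else
    data.frame(comparison = character(), protocol = character(),
               key = character(), metric = character(), id_a = character(),
               id_b = character(), value = numeric(), value_px = numeric(),
               unit = character())

  # limits of agreement + outliers per (comparison, metric, protocol)
  loa_rows <- list(); outliers <- list()
  if (nrow(differences)) {
    strata <- split(seq_len(nrow(differences)),
                    paste(differences$comparison, differences$metric,
                          differences$protocol, sep = "|"))
    for (nm in names(strata)) {
      idx <- strata[[nm]]
      if (length(idx) < 2L) next
      parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
      lo <- limits_of_agreement(differences$value[idx],
                                unit = differences$unit[idx][1L])
      loa_rows[[nm]] <- data.frame(
        comparison = parts[1L], metric = parts[2L], protocol = parts[3L],
        n = lo$n, mean = lo$mean, sd = lo$sd, lower = lo$lower,
        upper = lo$upper, unit = lo$unit, stringsAsFactors = FALSE)
      out <- idx[differences$value[idx] > lo$upper]
      if (length(out))
        outliers[[nm]] <- data.frame(
          comparison = parts[1L], metric = parts[2L],
          protocol = parts[3L], key = differences$key[out],
          id_a = differences$id_a[out], id_b = differences$id_b[out],
          value = differences$value[out], upper = lo$upper,
          stringsAsFactors = FALSE)
    }
  }
  loa <- if (length(loa_rows)) do.call(rbind, c(loa_rows,
                                                make.row.names = FALSE))
  else NULL
  outliers <- if (length(outliers)) do.call(rbind, c(outliers,
                                                     make.row.names = FALSE))
  else NULL

  icc <- list()
  complete_table <- function(df, row_key, col_key) {
    tab <- tapply(df$area_mm2, list(row_key, col_key), mean)
    tab[stats::complete.cases(tab), , drop = FALSE]
  }
  for (proto in unique(areas$protocol)) {
    a <- areas[areas$protocol == proto, , drop = FALSE]
    if ("intra_rater" %in% comparisons) {
      multi <- stats::ave(seq_len(nrow(a)),
                          paste(a$scan_id, a$rater_id),
                          FUN = length) > 1
      ai <- a[multi, , drop = FALSE]
      if (nrow(ai)) {
        sess <- stats::ave(ai$session_id, paste(ai$scan_id, ai$rater_id),
                           FUN = function(s) match(s, sort(unique(s))))
        tab <- complete_table(ai, paste(ai$scan_id, ai$rater_id),
                              paste0("session", sess))
        if (nrow(tab) >= 2L && ncol(tab) >= 2L)
          icc[[paste0("intra_rater|", proto)]] <-
            icc_two_way_random(tab)
      }
    }
    if ("inter_rater" %in% comparisons) {
      af <- a[!duplicated(paste(a$scan_id, a$rater_id)), , drop = FALSE]
      tab <- complete_table(af, af$scan_id, af$rater_id)
      if (nrow(tab) >= 2L && ncol(tab) >= 2L)
        icc[[paste0("inter_rater|", proto)]] <- icc_two_way_random(tab)
    }
    if ("inter_device" %in% comparisons && proto == "radial") {
      af <- a[!duplicated(paste(a$subject_id, a$device, a$rater_id)), ,
              drop = FALSE]
      tab <- complete_table(af, paste(af$subject_id, af$rater_id),
                            af$device)
      if (nrow(tab) >= 2L && ncol(tab) >= 2L)
        icc[[paste0("inter_device|", proto)]] <- icc_two_way_random(tab)
    }
  }

  # Bland-Altman per measurer pair on areas
  ba <- list()
  for (proto in unique(areas$protocol)) {
    a <- areas[areas$protocol == proto, , drop = FALSE]
    if ("inter_rater" %in% comparisons) {
      af <- a[!duplicated(paste(a$scan_id, a$rater_id)), , drop = FALSE]
      tab <- tapply(af$area_mm2, list(af$scan_id, af$rater_id), mean)
      tab <- tab[stats::complete.cases(tab), , drop = FALSE]
      if (nrow(tab) >= 2L)
        for (p in all_pairs(colnames(tab)))
          ba[[sprintf("inter_rater|%s|%s-%s", proto, p[1L], p[2L])]] <-
            bland_altman(tab[, p[1L]], tab[, p[2L]], unit = "mm2",
                         id_a = p[1L], id_b = p[2L])
    }
    if ("inter_device" %in% comparisons && proto == "radial") {
      af <- a[!duplicated(paste(a$subject_id, a$device, a$rater_id)), ,
              drop = FALSE]
      tab <- tapply(af$area_mm2,
                    list(paste(af$subject_id, af$rater_id), af$device),
                    mean)
      tab <- tab[stats::complete.cases(tab), , drop = FALSE]
      if (nrow(tab) >= 2L)
        for (p in all_pairs(colnames(tab)))
          ba[[sprintf("inter_device|%s|%s-%s", proto, p[1L], p[2L])]] <-
            bland_altman(tab[, p[1L]], tab[, p[2L]], unit = "mm2",
                         id_a = p[1L], id_b = p[2L])
    }
  }

  report <- structure(
    list(areas = areas, differences = differences, loa = loa,
         outliers = outliers, icc = icc, bland_altman = ba, log = log,
         config = list(half_width = half_width, step = step,
                       comparisons = comparisons)),
    class = "onh_study")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write a study report to CSV/JSON files
#'
#' Emits `areas.csv`, `differences.csv`, `loa.csv`, `bland_altman.csv` and
#' `icc.json` (comparison type, protocol, n, k, ICC) into `out_dir`.
#'
#' @param report an `onh_study` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "onh_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$areas, file.path(out_dir, "areas.csv"),
                   row.names = FALSE)
  utils::write.csv(report$differences,
                   file.path(out_dir, "differences.csv"), row.names = FALSE)
  if (!is.null(report$loa))
    utils::write.csv(report$loa, file.path(out_dir, "loa.csv"),
                     row.names = FALSE)
  ba_rows <- lapply(names(report$bland_altman), function(nm) {
    x <- report$bland_altman[[nm]]
    data.frame(pair = nm, n = x$loa$n, bias = x$bias,
               loa_lower = x$loa$lower, loa_upper = x$loa$upper,
               ci_bias_lo = x$ci_bias[1], ci_bias_hi = x$ci_bias[2],
               unit = x$unit, stringsAsFactors = FALSE)
  })
  if (length(ba_rows))
    utils::write.csv(do.call(rbind, ba_rows),
                     file.path(out_dir, "bland_altman.csv"),
                     row.names = FALSE)
  icc_block <- lapply(names(report$icc), function(nm) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    x <- report$icc[[nm]]
    list(comparison = parts[1L], protocol = parts[2L], n = x$n, k = x$k,
         type = x$type, icc = x$icc)
  })
  writeLines(jsonlite::toJSON(icc_block, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "icc.json"))
  if (length(report$log))
    writeLines(report$log, file.path(out_dir, "exclusions.log"))
  invisible(out_dir)
}

#' @export
print.onh_study <- function(x, ...) {
  cat("<onh_study>\n")
  cat(sprintf("  %d area measurements on %d scans (window %.3g mm, step %g um)\n",
              nrow(x$areas), length(unique(x$areas$scan_id)),
              2 * x$config$half_width, x$config$step))
  if (!is.null(x$loa)) {
    cat("  limits of agreement:\n")
    for (i in seq_len(nrow(x$loa)))
      cat(sprintf("    %-12s %-4s (%s): %.3f +/- 1.96 x %.3f %s -> upper %.3f\n",
                  x$loa$comparison[i], x$loa$metric[i], x$loa$protocol[i],
                  x$loa$mean[i], x$loa$sd[i], x$loa$unit[i],
                  x$loa$upper[i]))
  }
  if (length(x$icc)) {
    cat("  ICC (two-way random, absolute agreement, single measure):\n")
    for (nm in names(x$icc))
      cat(sprintf("    %-24s %.4f (n = %d, k = %d)\n", nm,
                  x$icc[[nm]]$icc, x$icc[[nm]]$n, x$icc[[nm]]$k))
  }
  n_out <- if (is.null(x$outliers)) 0L else nrow(x$outliers)
  cat(sprintf("  %d outlier(s) beyond the upper limit of agreement\n",
              n_out))
  if (length(x$log)) cat("  exclusions:", length(x$log), "\n")
  invisible(x)
}

#' @export
summary.onh_study <- function(object, ...) {
  x <- object
  cat("Study summary\n=============\n")
  print(x)
  if (nrow(x$areas)) {
    cat("\nArea range by protocol:\n")
    rng <- tapply(x$areas$area_mm2, x$areas$protocol, range)
    for (nm in names(rng))
      cat(sprintf("  %s: %.3f to %.3f mm^2\n", nm, rng[[nm]][1],
                  rng[[nm]][2]))
  }
  if (!is.null(x$outliers)) {
    cat("\nOutliers:\n")
    print(x$outliers, row.names = FALSE)
  }
  invisible(x)
}

#' Maximum absolute area difference per comparison type
#'
#' Convenience accessor mirroring the headline agreement ordering: the
#' maximum absolute area difference within raters, between raters and
#' between devices.
#'
#' @param report an `onh_study`.
#' @return Named numeric vector (mm^2) over the comparisons present.
#' @export
max_area_differences <- function(report) {
  stopifnot(inherits(report, "onh_study"))
  d <- report$differences
  d <- d[d$metric == "area", , drop = FALSE]
  if (!nrow(d)) return(stats::setNames(numeric(), character()))
  vapply(split(d$value, d$comparison), max, 0)
}
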