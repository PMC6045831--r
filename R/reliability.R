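#' 95% limits of agreement
#'
#' Computes the Bland--Altman style agreement interval for a set of values
#' (typically per-scan mean absolute segmentation differences, or paired
#' differences of areas): the sample mean plus/minus 1.96 times the sample
#' standard deviation (n - 1 denominator).
#'
#' @param values numeric vector, length >= 2.
#' @param unit unit label carried through to summaries (e.g. `"um"`,
#'   `"mm2"`).
#' @return A `loa_summary`: list with `n`, `mean`, `sd`, `lower`, `upper`,
#'   `unit`.
#' @examples
#' limits_of_agreement(c(0, 10))  # mean 5, sd 7.07, upper 18.86
#' @export
limits_of_agreement <- function(values, unit = "um") {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values))
    stop("'values' must hold at least 2 non-missing numbers")
  m <- mean(values); s <- stats::sd(values)
  structure(list(n = length(values), mean = m, sd = s,
                 lower = m - 1.96 * s, upper = m + 1.96 * s, unit = unit),
            class = "loa_summary")
}

#' @export
print.loa_summary <- function(x, ...) {
  cat(sprintf("<loa_summary> n = %d: %.3f +/- 1.96 x %.3f %s -> [%.3f, %.3f]\n",
              x$n, x$mean, x$sd, x$unit, x$lower, x$upper))
  invisible(x)
}

#' Flag outlying segmentation differences
#'
#' Identifies difference records whose per-scan mean absolute difference
#' exceeds (strictly) the upper limit of agreement. Absolute differences
#' cannot meaningfully breach a lower bound, so only the upper limit is
#' tested; a record exactly at the bound is not flagged.
#'
#' @param records list of `difference_pair` objects (or a data frame with a
#'   `mean_abs_diff_um` column and a `scan_id` column).
#' @param loa a `loa_summary` in micrometres.
#' @return Character vector of flagged `scan_id`s (with contributor ids
#'   appended for list input).
#' @export
flag_outliers <- function(records, loa) {
  stopifnot(inherits(loa, "loa_summary"))
  if (loa$unit != "um")
    stop("unit mismatch: limits of agreement must be in um")
  if (is.data.frame(records)) {
    vals <- records$mean_abs_diff_um
    ids <- records$scan_id
  } else {
    stopifnot(all(vapply(records, inherits, TRUE, "difference_pair")))
    vals <- vapply(records, `[[`, 0, "mean_abs_diff_um")
    ids <- vapply(records, function(r)
      paste(r$scan_id, r$id_a, r$id_b, sep = ":"), "")
  }
  ids[vals > loa$upper]
}

#' Two-way random absolute-agreement intraclass correlation
#'
#' Single-measure ICC with subjects and measurers (raters, sessions, or
#' devices) both treated as random effects and systematic measurer
#' differences penalized -- ICC(A,1) in McGraw--Wong terms. Computed from
#' the two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the between-subject,
#' between-measurer and residual mean squares of the complete n x k table.
#' The mean squares are computed internally from definitional sums of
#' squares. The average-measure variant ICC(A,k) is available via `type`.
#'
#' @param table numeric n x k matrix, rows = subjects, columns = measurers;
#'   complete (no missing cells), n >= 2, k >= 2.
#' @param type `"single"` (default, ICC(A,1)) or `"average"` (ICC(A,k)).
#' @return An `onh_icc`: list with `icc`, `type`, `n`, `k`, `ms` (the three
#'   mean squares).
#' @examples
#' m <- cbind(1:4, 1:4, 1:4)
#' icc_two_way_random(m)$icc  # exactly 1
#' @export
icc_two_way_random <- function(table, type = c("single", "average")) {
  type <- match.arg(type)
  table <- as.matrix(table)
  if (!is.numeric(table) || anyNA(table))
    stop("'table' must be a complete numeric matrix")
  n <- nrow(table); k <- ncol(table)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 measurers")
  grand <- mean(table)
  row_m <- rowMeans(table); col_m <- colMeans(table)
  ss_total <- sum((table - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total <= .Machine$double.eps * max(1, abs(grand))^2 * n * k)
    stop("table has zero total variance; ICC is undefined")
  icc <- if (type == "single") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  structure(list(icc = icc, type = type, n = n, k = k,
                 ms = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "onh_icc")
}

#' @export
print.onh_icc <- function(x, ...) {
  cat(sprintf("<onh_icc> two-way random, absolute agreement, %s measures\n",
              x$type))
  cat(sprintf("  ICC = %.6f  (n = %d subjects, k = %d measurers)\n",
              x$icc, x$n, x$k))
  invisible(x)
}

#' Bland--Altman agreement analysis for paired measurements
#'
#' For two paired measurement series (e.g. areas from two raters over the
#' same eyes), computes per-pair means and differences (`a - b`), the bias
#' (mean difference), the 95% limits of agreement of the differences, and
#' 95% confidence intervals: for the bias, `bias +/- t(0.975, n-1) * sd /
#' sqrt(n)`; for each agreement limit, `limit +/- t(0.975, n-1) * sd *
#' sqrt(3/n)`.
#'
#' @param a,b paired numeric vectors of equal length n >= 2; the difference
#'   sign convention is fixed as first argument minus second.
#' @param unit unit label.
#' @param id_a,id_b labels for the two measurers.
#' @return An `onh_ba`: list with `pairs` (data frame of means and
#'   differences), `bias`, `loa` (a `loa_summary`), `ci_bias`,
#'   `ci_lower`, `ci_upper`, ids and unit.
#' @export
bland_altman <- function(a, b, unit = "mm2", id_a = "A", id_b = "B") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 2L || anyNA(a) || anyNA(b))
    stop("need at least 2 complete pairs")
  d <- a - b
  loa <- limits_of_agreement(d, unit = unit)
  n <- loa$n
  tq <- stats::qt(0.975, df = n - 1)
  half_bias <- tq * loa$sd / sqrt(n)
  half_lim <- tq * loa$sd * sqrt(3 / n)
  structure(list(pairs = data.frame(mean = (a + b) / 2, diff = d),
                 bias = loa$mean, loa = loa,
                 ci_bias = c(loa$mean - half_bias, loa$mean + half_bias),
                 ci_lower = c(loa$lower - half_lim, loa$lower + half_lim),
                 ci_upper = c(loa$upper - half_lim, loa$upper + half_lim),
                 id_a = id_a, id_b = id_b, unit = unit),
            class = "onh_ba")
}

#' @export
print.onh_ba <- function(x, ...) {
  cat(sprintf("<onh_ba> %s - %s (n = %d)\n", x$id_a, x$id_b, x$loa$n))
  cat(sprintf("  bias %.4f %s  [95%% CI %.4f, %.4f]\n", x$bias, x$unit,
              x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  limits of agreement [%.4f, %.4f] %s\n", x$loa$lower,
              x$loa$upper, x$unit))
  invisible(x)
}

#' Bland--Altman plot
#'
#' Standard agreement plot: per-pair differences against per-pair means,
#' with the bias and both 95% limits of agreement drawn as horizontal
#' lines (dashed) and their confidence intervals as dotted lines.
#'
#' @param x an `onh_ba` from [bland_altman()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.onh_ba <- function(x, ...) {
  graphics::plot(x$pairs$mean, x$pairs$diff,
                 xlab = sprintf("Mean of %s and %s (%s)", x$id_a, x$id_b,
                                x$unit),
                 ylab = sprintf("%s - %s (%s)", x$id_a, x$id_b, x$unit),
                 ylim = range(x$pairs$diff, x$ci_lower, x$ci_upper), ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa$lower, x$loa$upper), lty = 2)
  graphics::abline(h = c(x$ci_lower, x$ci_upper), lty = 3, col = "grey50")
  invisible(x)
}
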