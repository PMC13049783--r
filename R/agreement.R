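# Agreement statistics: Bland-Altman, Pearson correlation, cohort summary.

#' Bland-Altman agreement analysis
#'
#' Differences are estimate minus reference (`y - x`); the bias is their
#' mean, the spread their sample standard deviation (n - 1 denominator by
#' default), and the limits of agreement are `bias -/+ multiplier * SD`
#' with the conventional 1.96 multiplier.
#'
#' @param x Reference values.
#' @param y Estimated values (same length, pairwise finite).
#' @param multiplier Width of the limits in standard deviations.
#' @param sd_type `"sample"` (n - 1) or `"population"` (n).
#' @return A list of class `bland_altman`: `bias`, `sd`, `lower`, `upper`,
#'   `n`.
#' @export
bland_altman <- function(x, y, multiplier = 1.96,
                         sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  if (sd_type == "population") s <- s * sqrt((length(d) - 1) / length(d))
  structure(list(bias = bias, sd = s,
                 lower = bias - multiplier * s,
                 upper = bias + multiplier * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman: bias %.3f +/- %.3f, limits [%.3f, %.3f], n = %d>\n",
              x$bias, x$sd, x$lower, x$upper, x$n))
  invisible(x)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the usual t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant input")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Summarize threshold agreement over a cohort
#'
#' Detection rate over all subjects; workload (same-stage) accuracy among
#' detected subjects; the within-20-s rate under both denominator
#' conventions (all subjects, and detected-only). Exact fractions are kept
#' alongside percentages rounded to one decimal.
#'
#' @param agreements List of `at_agreement` objects
#'   (see [evaluate_at_agreement()]).
#' @return A list of class `cohort_summary`.
#' @export
summarize_at_cohort <- function(agreements) {
  if (length(agreements) == 0L) stop("empty agreement list")
  det <- vapply(agreements, function(a) isTRUE(a$detected), logical(1))
  same <- vapply(agreements, function(a) isTRUE(a$same_stage), logical(1))
  w20 <- vapply(agreements, function(a) isTRUE(a$within_20s), logical(1))
  n <- length(agreements)
  n_det <- sum(det)
  out <- list(n = n, n_detected = n_det,
              detection_rate = n_det / n,
              workload_accuracy = if (n_det > 0) sum(same & det) / n_det else NA_real_,
              within_20s_all = sum(w20) / n,
              within_20s_detected = if (n_det > 0) sum(w20 & det) / n_det else NA_real_)
  out$percent <- lapply(out[c("detection_rate", "workload_accuracy",
                              "within_20s_all", "within_20s_detected")],
                        function(f) round(100 * f, 1))
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0("<cohort_summary: n = %d; detection %.1f%%; workload ",
                     "accuracy %.1f%%; within 20 s %.1f%% (all) / %.1f%% ",
                     "(detected)>\n"),
              x$n, 100 * x$detection_rate, 100 * x$workload_accuracy,
              100 * x$within_20s_all, 100 * x$within_20s_detected))
  invisible(x)
}

#' Render a cohort summary as a small Markdown table
#'
#' @param summaries Named list of `cohort_summary` objects (one per
#'   feature, e.g. energy and intensity).
#' @return Character vector of Markdown lines.
#' @export
summary_markdown <- function(summaries) {
  hdr <- paste0("| | ", paste(names(summaries), collapse = " | "), " |")
  sep <- paste0("|---", strrep("|---", length(summaries)), "|")
  row <- function(label, field) {
    vals <- vapply(summaries, function(s) sprintf("%.1f%%", 100 * s[[field]]),
                   character(1))
    paste0("| ", label, " | ", paste(vals, collapse = " | "), " |")
  }
  c(hdr, sep,
    row("Successful detection", "detection_rate"),
    row("Accuracy of workload", "workload_accuracy"),
    row("Time difference <= 20 s", "within_20s_all"))
}
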