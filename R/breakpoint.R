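# Anaerobic-threshold detection: two-segment breakpoint fit on an acoustic
# feature trace, ventilatory-equivalents reference, and agreement scoring.

#' Continuous two-segment least-squares breakpoint fit
#'
#' Exhaustive search over candidate breakpoints on the sample grid
#' (excluding `margin` samples at each end). At each candidate the model is
#' two straight segments constrained to meet at the breakpoint
#' (`y = a + b1 * min(t - tc, 0) + b2 * max(t - tc, 0)`), fitted by ordinary
#' least squares; the candidate minimizing the residual sum of squares wins,
#' with ties broken toward the earliest time. The single-line fit provides
#' the reference SSE for the improvement ratio `1 - SSE2/SSE1`.
#'
#' @param times Strictly increasing sample times, seconds.
#' @param values Feature values.
#' @param margin Number of samples excluded at each end of the candidate
#'   grid.
#' @return A list of class `breakpoint_fit`: `breakpoint`, `value` (fitted
#'   value at the breakpoint), `slope_before`, `slope_after`, `sse2`,
#'   `sse1`, `improvement`, `n`.
#' @export
fit_two_segment <- function(times, values, margin = 3L) {
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  n <- length(times)
  if (n < 8L) stop("need at least 8 samples for a two-segment fit")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")

  line_fit <- stats::.lm.fit(cbind(1, times), values)
  sse1 <- sum(line_fit$residuals^2)

  best_sse <- Inf
  best <- NULL
  for (i in seq(margin + 1L, n - margin)) {
    tc <- times[i]
    X <- cbind(1, pmin(times - tc, 0), pmax(times - tc, 0))
    f <- stats::.lm.fit(X, values)
    sse <- sum(f$residuals^2)
    if (sse < best_sse * (1 - 1e-12) || is.null(best)) {
      best_sse <- sse
      best <- list(i = i, coef = f$coefficients)
    }
  }
  sse2 <- min(best_sse, sse1)
  improvement <- if (sse1 > .Machine$double.eps) max(0, 1 - best_sse / sse1) else 0
  structure(list(breakpoint = times[best$i],
                 value = best$coef[1],
                 slope_before = best$coef[2],
                 slope_after = best$coef[3],
                 sse2 = sse2, sse1 = sse1,
                 improvement = improvement, n = n),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(paste0("<breakpoint_fit: knee at %.1f s, slopes %.4g -> %.4g, ",
                     "improvement %.3f (n = %d)>\n"),
              x$breakpoint, x$slope_before, x$slope_after, x$improvement, x$n))
  invisible(x)
}

#' Validity rules for acoustic threshold detection
#'
#' @param improvement_min Minimum improvement ratio of the two-segment fit
#'   over a single line for the breakpoint to count as a detection.
#' @param end_margin Breakpoints closer than this (seconds) to either end of
#'   the exercise phase are rejected.
#' @return A list of class `at_params`.
#' @export
at_params <- function(improvement_min = 0.2, end_margin = 60) {
  structure(list(improvement_min = improvement_min, end_margin = end_margin),
            class = "at_params")
}

#' Detect the anaerobic threshold from an acoustic feature trace
#'
#' Restricts the feature series to the exercise phase (warmup and recovery
#' dropped), fits the two-segment breakpoint model to the chosen feature,
#' and declares a detection only when (a) the improvement ratio reaches
#' `improvement_min`, (b) the slope steepens at the breakpoint
#' (ventilation accelerates at the threshold, it never slows), and (c) the
#' breakpoint is not within `end_margin` seconds of either end of the
#' fitted span. On detection the time is mapped to its protocol stage and
#' workload.
#'
#' @param series A `feature_series` from [build_feature_series()].
#' @param feature `"intensity"` or `"energy"`.
#' @param protocol The `protocol_spec`.
#' @param params An [at_params()].
#' @return A list of class `at_detection`: `detected`, `time`, `stage`,
#'   `workload`, `feature`, `fit` (the `breakpoint_fit`, kept for
#'   diagnostics also when detection fails).
#' @export
detect_at_acoustic <- function(series, feature = c("intensity", "energy"),
                               protocol, params = at_params()) {
  feature <- match.arg(feature)
  if (!feature %in% names(series)) stop("feature channel missing: ", feature)
  ex <- series$stage > 0L & !series$missing & is.finite(series[[feature]])
  t <- series$time[ex]
  y <- series[[feature]][ex]
  if (length(t) < 8L) stop("feature series does not cover the exercise phase")

  fit <- fit_two_segment(t, y)
  span <- range(t)
  valid <- fit$improvement >= params$improvement_min &&
    fit$slope_after > fit$slope_before &&
    fit$breakpoint >= span[1] + params$end_margin &&
    fit$breakpoint <= span[2] - params$end_margin

  if (valid) {
    sw <- stage_at_time(protocol, fit$breakpoint)
    structure(list(detected = TRUE, time = fit$breakpoint,
                   stage = sw$stage, workload = sw$workload,
                   feature = feature, fit = fit),
              class = "at_detection")
  } else {
    structure(list(detected = FALSE, time = NA_real_, stage = NA_integer_,
                   workload = NA_real_, feature = feature, fit = fit),
              class = "at_detection")
  }
}

#' Reference ventilatory threshold from the ventilatory equivalents
#'
#' The VE/VO2 trace is smoothed with a centred rolling median over
#' `smooth_breaths` breaths and its global minimum (nadir) over the
#' exercise phase is located; the exact breath is then refined to the raw
#' minimum within `refine_breaths` breaths of the smoothed nadir, which
#' removes the smoothing bias of an asymmetric nadir. The candidate is
#' accepted only if the VE/VCO2 trace is still flat or decreasing there
#' (local linear slope over `slope_window` seconds at most `slope_tol`);
#' otherwise the earliest interior local minimum satisfying the check is
#' used, and if none does the reference is flagged undetermined. A nadir on
#' the boundary of the exercise phase is rejected.
#'
#' @param gas A [gas_exchange_series()] covering the exercise phase.
#' @param protocol The `protocol_spec`.
#' @param body_mass Kilograms, used to normalize the oxygen uptake at the
#'   threshold.
#' @param smooth_breaths Rolling-median width, breaths (odd).
#' @param refine_breaths Half-width of the raw-minimum refinement, breaths.
#' @param slope_window Window for the local VE/VCO2 slope, seconds.
#' @param slope_tol Acceptance tolerance on the VE/VCO2 slope, units/s.
#' @return A list of class `reference_at`: `determined`, `time`, `stage`,
#'   `workload`, `vo2_at_kg` (10-s-averaged, mL/kg/min).
#' @export
reference_at_ventilatory <- function(gas, protocol, body_mass,
                                     smooth_breaths = 7, refine_breaths = 4,
                                     slope_window = 60, slope_tol = 0.002) {
  eq <- ventilatory_equivalents(gas)
  span <- exercise_span(protocol)
  ex <- which(eq$time >= span[1] & eq$time < span[2])
  undetermined <- structure(list(determined = FALSE, time = NA_real_,
                                 stage = NA_integer_, workload = NA_real_,
                                 vo2_at_kg = NA_real_),
                            class = "reference_at")
  if (length(ex) < smooth_breaths + 2L) return(undetermined)

  k <- smooth_breaths
  if (k %% 2L == 0L) k <- k + 1L
  sm_vo2 <- stats::runmed(eq$ve_vo2, k, endrule = "median")
  sm_vco2 <- stats::runmed(eq$ve_vco2, k, endrule = "median")

  slope_ok <- function(i) {
    win <- which(abs(eq$time - eq$time[i]) <= slope_window / 2)
    if (length(win) < 3L) return(FALSE)
    b <- stats::.lm.fit(cbind(1, eq$time[win]), sm_vco2[win])$coefficients[2]
    b <= slope_tol
  }
  refine <- function(i) {
    cand <- ex[abs(ex - i) <= refine_breaths]
    cand[which.min(eq$ve_vo2[cand])]
  }
  interior <- function(i) i != ex[1] && i != ex[length(ex)]

  i_glob <- ex[which.min(sm_vo2[ex])]
  pick <- NA_integer_
  if (interior(i_glob) && slope_ok(i_glob)) {
    pick <- i_glob
  } else {
    # earliest interior local minimum of the smoothed trace passing the check
    v <- sm_vo2[ex]
    loc <- ex[which(diff(sign(diff(v))) > 0) + 1L]
    for (i in loc) {
      if (interior(i) && slope_ok(i)) { pick <- i; break }
    }
  }
  if (is.na(pick)) return(undetermined)

  i_ref <- refine(pick)
  at_time <- eq$time[i_ref]
  sw <- stage_at_time(protocol, at_time)
  structure(list(determined = TRUE, time = at_time,
                 stage = sw$stage, workload = sw$workload,
                 vo2_at_kg = .vo2_10s_at(gas, at_time) / body_mass),
            class = "reference_at")
}

#' Score agreement between acoustic and reference thresholds
#'
#' @param est An `at_detection`.
#' @param ref A determined `reference_at`.
#' @param gas The gas-exchange series (for the oxygen-uptake error).
#' @param protocol The `protocol_spec`.
#' @return A list of class `at_agreement`: `detected`, `same_stage`,
#'   `time_diff` (estimate minus reference, seconds; `NA` when
#'   undetected), `within_20s`, `vo2_rel_err`.
#' @export
evaluate_at_agreement <- function(est, ref, gas, protocol) {
  if (!isTRUE(ref$determined)) stop("reference threshold is undetermined")
  if (!est$detected) {
    return(structure(list(detected = FALSE, same_stage = FALSE,
                          time_diff = NA_real_, within_20s = FALSE,
                          vo2_rel_err = NA_real_),
                     class = "at_agreement"))
  }
  dt <- est$time - ref$time
  v_ref <- .vo2_10s_at(gas, ref$time)
  v_est <- .vo2_10s_at(gas, est$time)
  structure(list(detected = TRUE,
                 same_stage = identical(est$stage, ref$stage),
                 time_diff = dt,
                 within_20s = abs(dt) <= 20,
                 vo2_rel_err = abs(v_est - v_ref) / v_ref),
            class = "at_agreement")
}

#' V-slope breakpoint (optional cross-check)
#'
#' Two-segment fit of VCO2 against VO2 (both 10-s bin means). The
#' breakpoint abscissa is the oxygen uptake at the threshold; the
#' corresponding time is the first bin whose mean VO2 exceeds it.
#'
#' @param gas A [gas_exchange_series()].
#' @param protocol The `protocol_spec`.
#' @return A list with `vo2_at` (mL/min), `time` (s) and the underlying
#'   `breakpoint_fit`.
#' @export
vslope_at <- function(gas, protocol) {
  span <- exercise_span(protocol)
  b <- gas$breaths[gas$breaths$time >= span[1] & gas$breaths$time < span[2], ]
  bin <- floor((b$time - span[1]) / 10)
  vo2 <- tapply(b$vo2, bin, mean)
  vco2 <- tapply(b$vco2, bin, mean)
  tmid <- tapply(b$time, bin, mean)
  o <- order(vo2)
  vo2s <- as.numeric(vo2[o]); vco2s <- as.numeric(vco2[o])
  keep <- c(TRUE, diff(vo2s) > 0)
  fit <- fit_two_segment(vo2s[keep], vco2s[keep])
  i <- which(vo2 >= fit$breakpoint)[1]
  list(vo2_at = fit$breakpoint, time = as.numeric(tmid[i]), fit = fit)
}
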