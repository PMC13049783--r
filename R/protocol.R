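# The stepwise incremental exercise protocol: warmup, fixed-length stages
# with an individualized workload increment, and active recovery.

#' Subject profile
#'
#' @param age Years; the inclusion range is 18-65 and values outside it
#'   raise a warning (not an error).
#' @param sex `"F"` or `"M"`.
#' @param height Centimetres.
#' @param weight Kilograms.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(age, sex = c("F", "M"), height, weight) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(age), length(age) == 1L, height > 0, weight > 0)
  if (age < 18 || age > 65) {
    warning("age ", age, " is outside the 18-65 y inclusion range")
  }
  structure(list(age = age, sex = sex, height = height, weight = weight),
            class = "subject_profile")
}

#' Age-predicted maximal heart rate and the submaximal termination threshold
#'
#' `predicted_hr_max()` is the classic 220 - age; the test is terminated at
#' `fraction` (default 85%) of it.
#'
#' @param profile A [subject_profile()].
#' @return Beats per minute.
#' @export
predicted_hr_max <- function(profile) 220 - profile$age

#' @rdname predicted_hr_max
#' @param fraction Fraction of the predicted maximum.
#' @export
hr_submax_threshold <- function(profile, fraction = 0.85) {
  fraction * predicted_hr_max(profile)
}

#' Coefficients of the workload-increment prediction formulas
#'
#' Unloaded oxygen uptake is `unloaded_intercept + unloaded_per_kg * weight`
#' (mL/min). Predicted peak oxygen uptake uses the standard sedentary
#' formulas: `weight * (male_slope - male_age * age)` for men and
#' `(weight + female_mass_offset) * (female_slope - female_age * age)` for
#' women. Every coefficient can be overridden.
#'
#' @param unloaded_intercept,unloaded_per_kg,male_slope,male_age,female_slope,female_age,female_mass_offset
#'   Numeric coefficients.
#' @return A named list.
#' @export
wasserman_coefficients <- function(unloaded_intercept = 150, unloaded_per_kg = 6,
                                   male_slope = 50.72, male_age = 0.372,
                                   female_slope = 22.78, female_age = 0.17,
                                   female_mass_offset = 43) {
  list(unloaded_intercept = unloaded_intercept, unloaded_per_kg = unloaded_per_kg,
       male_slope = male_slope, male_age = male_age,
       female_slope = female_slope, female_age = female_age,
       female_mass_offset = female_mass_offset)
}

#' Individualized workload increment per stage
#'
#' The per-minute ramp rate is `(predicted peak VO2 - unloaded VO2) / 100`
#' Watts per minute; the formulas were designed for 1-min incremental
#' stages, so for `stage_min`-minute stages the increment is scaled by the
#' stage length (doubled for the default 2-min stepwise protocol) and then
#' rounded to the nearest `round_to` Watts.
#'
#' @param profile A [subject_profile()].
#' @param coef A [wasserman_coefficients()] list.
#' @param stage_min Stage length in minutes.
#' @param round_to Rounding granularity in Watts (`0` disables rounding).
#' @return Watts per stage.
#' @export
workload_increment <- function(profile, coef = wasserman_coefficients(),
                               stage_min = 2, round_to = 5) {
  unloaded <- coef$unloaded_intercept + coef$unloaded_per_kg * profile$weight
  peak <- if (profile$sex == "M") {
    profile$weight * (coef$male_slope - coef$male_age * profile$age)
  } else {
    (profile$weight + coef$female_mass_offset) *
      (coef$female_slope - coef$female_age * profile$age)
  }
  ramp <- (peak - unloaded) / 100
  if (!is.finite(ramp) || ramp <= 0) {
    stop("non-positive predicted ramp rate; check profile and coefficients")
  }
  inc <- stage_min * ramp
  if (round_to > 0) inc <- max(round_to, round(inc / round_to) * round_to)
  inc
}

#' Build a stepwise protocol
#'
#' Warmup at the unloaded baseline, `n_stages` exercise stages whose
#' workload grows by exactly `increment_w` per stage, then active recovery.
#' All intervals are half-open `[start, end)`. Stage indexing: warmup is
#' stage 0, exercise stages are 1..n, recovery is the sentinel stage -1.
#'
#' @param increment_w Watts added per stage.
#' @param n_stages Number of exercise stages (>= 1).
#' @param warmup_s,stage_s,recovery_s Durations, seconds.
#' @param baseline_w Unloaded warmup workload, Watts.
#' @return A list of class `protocol_spec` with a `boundaries` data frame
#'   (`stage`, `start`, `end`, `workload`).
#' @export
build_protocol <- function(increment_w, n_stages, warmup_s = 180,
                           stage_s = 120, recovery_s = 120, baseline_w = 0) {
  stopifnot(n_stages >= 1, increment_w > 0, warmup_s >= 0, stage_s > 0)
  stage <- c(0L, seq_len(n_stages), -1L)
  start <- c(0, warmup_s + stage_s * (seq_len(n_stages) - 1),
             warmup_s + stage_s * n_stages)
  end <- c(start[-1], start[length(start)] + recovery_s)
  workload <- c(baseline_w, baseline_w + increment_w * seq_len(n_stages),
                NA_real_)
  structure(list(warmup_s = warmup_s, stage_s = stage_s,
                 increment_w = increment_w, n_stages = as.integer(n_stages),
                 recovery_s = recovery_s, baseline_w = baseline_w,
                 boundaries = data.frame(stage = stage, start = start,
                                         end = end, workload = workload)),
            class = "protocol_spec")
}

#' Protocol built from a subject profile
#' @param profile A [subject_profile()].
#' @param n_stages Number of exercise stages.
#' @param ... Passed to [workload_increment()] and [build_protocol()].
#' @export
protocol_for_subject <- function(profile, n_stages = 5, ...) {
  dots <- list(...)
  inc_args <- dots[names(dots) %in% c("coef", "stage_min", "round_to")]
  bp_args <- dots[names(dots) %in% c("warmup_s", "stage_s", "recovery_s", "baseline_w")]
  inc <- do.call(workload_increment, c(list(profile), inc_args))
  do.call(build_protocol, c(list(increment_w = inc, n_stages = n_stages), bp_args))
}

#' Total protocol duration (end of recovery), seconds
#' @param protocol A `protocol_spec`.
#' @export
protocol_duration <- function(protocol) {
  max(protocol$boundaries$end)
}

#' Start and end of the exercise phase (excluding warmup and recovery)
#' @param protocol A `protocol_spec`.
#' @return `c(start, end)` in seconds.
#' @export
exercise_span <- function(protocol) {
  b <- protocol$boundaries
  ex <- b[b$stage > 0L, ]
  c(min(ex$start), max(ex$end))
}

#' Map times to protocol stages
#'
#' Half-open convention: a time exactly on a boundary belongs to the later
#' interval. Warmup is stage 0; recovery is the sentinel stage -1 with `NA`
#' workload.
#'
#' @param protocol A `protocol_spec`.
#' @param t Numeric vector of times, seconds; all must lie in
#'   `[0, protocol end)`.
#' @return Data frame with `stage` and `workload`.
#' @export
stage_at_time <- function(protocol, t) {
  b <- protocol$boundaries
  if (any(t < 0 | t >= protocol_duration(protocol))) {
    stop("time outside the protocol span [0, ", protocol_duration(protocol), ")")
  }
  i <- findInterval(t, b$start)
  data.frame(stage = b$stage[i], workload = b$workload[i])
}

#' Serialize / load a protocol as YAML
#' @param protocol A `protocol_spec`.
#' @param path File path.
#' @export
write_protocol_yaml <- function(protocol, path) {
  yaml::write_yaml(list(warmup_s = protocol$warmup_s, stage_s = protocol$stage_s,
                        increment_w = protocol$increment_w,
                        n_stages = protocol$n_stages,
                        recovery_s = protocol$recovery_s,
                        baseline_w = protocol$baseline_w),
                   path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  build_protocol(increment_w = y$increment_w, n_stages = y$n_stages,
                 warmup_s = y$warmup_s, stage_s = y$stage_s,
                 recovery_s = y$recovery_s, baseline_w = y$baseline_w)
}
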