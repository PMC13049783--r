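# Synthetic CPET generator: ground-truth physiology (threshold time, peak
# oxygen uptake, breathing-rate trajectory) plus matching gas exchange and
# tracheal audio, so every pipeline stage is testable without recordings.
#
# The generator encodes the physiological chain that motivates acoustic
# threshold detection: above the anaerobic threshold the buffering of lactic
# acid produces excess CO2, minute ventilation (proportional to VCO2 plus a
# small hypocapnic drive) accelerates, and tracheal sound intensity - which
# tracks airflow linearly - inherits the breakpoint. VE/VO2 therefore
# reaches its nadir exactly at the threshold while VE/VCO2 is still
# decreasing there.

#' Simulation configuration
#'
#' @param n Cohort size.
#' @param seed Master seed; all randomness derives from it.
#' @param snr_db Segmental signal-to-noise ratio of the synthetic audio
#'   (mean in-burst signal power over stationary ambient power), dB.
#' @param cv_breath Coefficient of variation of the shared per-breath
#'   tidal-volume fluctuation applied multiplicatively to VE, VO2 and VCO2.
#' @param cv_channel Additional independent per-channel measurement noise
#'   (CV).
#' @param cv_coupling Per-breath scatter (CV, power domain) of the
#'   intensity-to-ventilation coupling.
#' @param spike_rate Motion-artifact rate, events per minute.
#' @param n_stages Exercise stages per subject.
#' @param rate Audio sampling rate, Hz (the device's native rate).
#' @param warmup_s,stage_s,recovery_s Protocol durations, seconds.
#' @param include_audio Attach synthesized audio to each cohort record
#'   (memory-heavy; the pipeline synthesizes audio lazily when `FALSE`).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n = 24, seed = 1, snr_db = 10,
                              cv_breath = 0.05, cv_channel = 0.003,
                              cv_coupling = 0.03, spike_rate = 2,
                              n_stages = 5, rate = 15277,
                              warmup_s = 180, stage_s = 120, recovery_s = 120,
                              include_audio = FALSE) {
  stopifnot(n >= 1)
  structure(list(n = n, seed = seed, snr_db = snr_db, cv_breath = cv_breath,
                 cv_channel = cv_channel, cv_coupling = cv_coupling,
                 spike_rate = spike_rate, n_stages = n_stages, rate = rate,
                 warmup_s = warmup_s, stage_s = stage_s,
                 recovery_s = recovery_s, include_audio = include_audio),
            class = "simulation_config")
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw one synthetic subject
#'
#' Demographics match the target cohort moments (age 31 +/- 9.1 y, 75%
#' female, BMI 23.5 +/- 3.3, peak oxygen uptake 27.1 +/- 6.7 mL/kg/min);
#' the true threshold time is uniform within 45-70% of the duration up to
#' the end of exercise. All draws are reproducible from `seed`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed for this subject.
#' @return A list of class `synthetic_subject`; the matching protocol is in
#'   `$protocol`.
#' @export
simulate_subject <- function(cfg = simulation_config(), seed = 1L) {
  set.seed(seed)
  sex <- if (runif(1) < 0.75) "F" else "M"
  age <- .clamp(rnorm(1, 31, 9.1), 18, 65)
  height <- if (sex == "F") rnorm(1, 165, 6) else rnorm(1, 178, 7)
  bmi <- .clamp(rnorm(1, 23.5, 3.3), 17, 35)
  weight <- bmi * (height / 100)^2
  profile <- subject_profile(age = age, sex = sex, height = height,
                             weight = weight)
  protocol <- protocol_for_subject(profile, n_stages = cfg$n_stages,
                                   warmup_s = cfg$warmup_s,
                                   stage_s = cfg$stage_s,
                                   recovery_s = cfg$recovery_s)

  # the achieved (protocol-limited) peak is ~83% of the predicted sedentary
  # capacity - the test stops at 85% of predicted maximal heart rate - with
  # individual scatter; this both ties the peak to the demographics, as in
  # real cohorts, and reproduces the target moments (27.1 +/- 6.7 mL/kg/min)
  wc <- wasserman_coefficients()
  pred_peak <- if (sex == "M") {
    weight * (wc$male_slope - wc$male_age * age)
  } else {
    (weight + wc$female_mass_offset) * (wc$female_slope - wc$female_age * age)
  }
  vo2peak_kg <- .clamp(0.83 * pred_peak / weight * exp(rnorm(1, 0, 0.18)), 15, 60)
  vo2_0 <- 150 + 6 * weight
  vo2peak <- max(vo2peak_kg * weight, 1.4 * vo2_0)
  ex_end <- exercise_span(protocol)[2]
  at_time <- runif(1, 0.45, 0.70) * ex_end
  at_time <- .clamp(at_time, protocol$warmup_s + 30, ex_end - 90)

  rr_start <- runif(1, 12, 16)
  rr_end <- runif(1, 28, 38)

  rer_below <- 0.95
  rer_above <- 1.40
  ve_intercept <- weight / 12              # dead-space component, L/min
  ve_slope <- 26                           # L per L of VCO2
  plateau_s <- 20

  subj <- list(profile = profile, protocol = protocol, seed = as.integer(seed),
               at_time = at_time, vo2peak_kg = vo2peak / weight,
               vo2peak = vo2peak, vo2_0 = vo2_0,
               rr_start = rr_start, rr_end = rr_end,
               rer_below = rer_below, rer_above = rer_above,
               ve_intercept = ve_intercept, ve_slope = ve_slope,
               plateau_s = plateau_s,
               coupling = 0.004 * exp(rnorm(1, 0, 0.1)),
               hr_rest = runif(1, 65, 85),
               cv_breath = cfg$cv_breath, cv_channel = cfg$cv_channel,
               cv_coupling = cfg$cv_coupling,
               snr_db = cfg$snr_db, spike_rate = cfg$spike_rate,
               rate = cfg$rate)

  # hypocapnic post-threshold ventilatory drive, capped so VE/VCO2 is still
  # decreasing at the threshold (cap = intercept * rer_above / VCO2_at)
  vo2_at <- .vo2_model(subj, at_time)
  vco2_at_l <- rer_below * vo2_at / 1000
  subj$vo2_at <- vo2_at
  subj$ve_drive <- 0.75 * ve_intercept * rer_above / vco2_at_l
  class(subj) <- "synthetic_subject"
  subj
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_subject: %s, %.0f y, %.0f kg; AT %.0f s, ",
                     "VO2peak %.1f mL/kg/min, seed %d>\n"),
              x$profile$sex, x$profile$age, x$profile$weight,
              x$at_time, x$vo2peak_kg, x$seed))
  invisible(x)
}

# Deterministic oxygen-uptake trajectory (mL/min): constant unloaded value
# through warmup, linear rise to the peak, a short plateau at the peak at
# the end of exercise (so the 10-s-average peak equals the programmed peak
# exactly), exponential recovery.
.vo2_model <- function(subj, t) {
  proto <- subj$protocol
  ex <- exercise_span(proto)
  ramp_end <- ex[2] - subj$plateau_s
  v <- numeric(length(t))
  v[t < ex[1]] <- subj$vo2_0
  ramp <- t >= ex[1] & t < ramp_end
  v[ramp] <- subj$vo2_0 + (subj$vo2peak - subj$vo2_0) *
    (t[ramp] - ex[1]) / (ramp_end - ex[1])
  v[t >= ramp_end & t < ex[2]] <- subj$vo2peak
  rec <- t >= ex[2]
  v[rec] <- subj$vo2_0 + (subj$vo2peak - subj$vo2_0) * exp(-(t[rec] - ex[2]) / 45)
  v
}

# VCO2 (mL/min) and VE (L/min) from the oxygen-uptake trajectory; the VCO2
# slope steepens from rer_below to rer_above at the threshold and VE adds a
# capped linear post-threshold drive.
.gas_model <- function(subj, t) {
  vo2 <- .vo2_model(subj, t)
  excess <- pmax(vo2 - subj$vo2_at, 0)
  vco2 <- subj$rer_below * pmin(vo2, subj$vo2_at) + subj$rer_above * excess
  ve <- subj$ve_intercept + subj$ve_slope * vco2 / 1000 +
    subj$ve_drive * excess / 1000
  list(vo2 = vo2, vco2 = vco2, ve = ve)
}

#' Programmed (true) respiratory rate of a synthetic subject
#'
#' Linear ramp from `rr_start` at the protocol start to `rr_end` at the end
#' of exercise, constant afterwards.
#'
#' @param subj A `synthetic_subject`.
#' @param t Times, seconds.
#' @return Breaths per minute.
#' @export
true_rr <- function(subj, t) {
  ex_end <- exercise_span(subj$protocol)[2]
  subj$rr_start + (subj$rr_end - subj$rr_start) * .clamp(t / ex_end, 0, 1)
}

# Breath onsets from the programmed rate with a small (2% CV) interval
# jitter; deterministic given the subject's seed and shared between the gas
# and audio generators.
.breath_schedule <- function(subj) {
  set.seed(subj$seed + 7919L)
  t_end <- protocol_duration(subj$protocol)
  onsets <- numeric(0)
  t <- runif(1, 0, 60 / true_rr(subj, 0))
  while (t < t_end) {
    onsets <- c(onsets, t)
    t <- t + (60 / true_rr(subj, t)) * exp(rnorm(1, 0, 0.02))
  }
  onsets
}

#' Simulate breath-by-breath gas exchange
#'
#' Breath times follow the programmed breathing-rate ramp. Each breath's
#' VE, VO2 and VCO2 carry a shared multiplicative tidal-volume fluctuation
#' (`cv_breath`) plus small independent channel noise (`cv_channel`); the
#' shared factor cancels in the ventilatory equivalents, which is what
#' keeps the VE/VO2 nadir identifiable at realistic breath-to-breath
#' variability. Heart rate ramps from rest to 85% of (220 - age) at the
#' end of exercise on its own 5-s time base. The simulation ground truth is
#' attached as attribute `"truth"`.
#'
#' @param subj A [simulate_subject()] result.
#' @param protocol Protocol (defaults to the subject's own).
#' @return A [gas_exchange_series()] with attribute `"truth"`.
#' @export
simulate_gas_exchange <- function(subj, protocol = subj$protocol) {
  ex <- exercise_span(protocol)
  if (subj$at_time <= ex[1] || subj$at_time >= ex[2]) {
    stop("threshold time lies outside the exercise phase")
  }
  tb <- .breath_schedule(subj)
  nb <- length(tb)
  g <- .gas_model(subj, tb)

  set.seed(subj$seed + 104729L)
  shared <- exp(rnorm(nb, 0, subj$cv_breath))
  vo2 <- g$vo2 * shared * exp(rnorm(nb, 0, subj$cv_channel))
  vco2 <- g$vco2 * shared * exp(rnorm(nb, 0, subj$cv_channel))
  ve <- g$ve * shared * exp(rnorm(nb, 0, subj$cv_channel))
  intervals <- c(diff(tb), 60 / true_rr(subj, tb[nb]))
  vt <- ve * intervals / 60

  hr_t <- seq(0, protocol_duration(protocol), by = 5)
  hr_end <- 0.85 * predicted_hr_max(subj$profile)
  hr <- subj$hr_rest + (hr_end - subj$hr_rest) * .clamp(hr_t / ex[2], 0, 1)
  rec <- hr_t > ex[2]
  hr[rec] <- subj$hr_rest + (hr_end - subj$hr_rest) * exp(-(hr_t[rec] - ex[2]) / 60)
  hr <- hr + rnorm(length(hr), 0, 1.5)

  gas <- gas_exchange_series(tb, vo2, vco2, ve, vt = vt, hr = hr, hr_time = hr_t)
  attr(gas, "truth") <- list(at_time = subj$at_time,
                             vo2peak_kg = subj$vo2peak_kg,
                             vo2_at_kg = subj$vo2_at / subj$profile$weight,
                             weight = subj$profile$weight)
  gas
}

#' Synthesize tracheal audio for a synthetic subject
#'
#' Two band-limited noise bursts per breath (inspiration and a softer
#' expiration) with smooth raised-cosine ramps; each breath's mean-square
#' burst power is `coupling * VE` at that breath (sound intensity tracks
#' airflow linearly) with per-breath coupling scatter. Stationary ambient
#' noise shaped to the same 100-3000 Hz band is added at the configured
#' segmental SNR, and sparse high-amplitude motion spikes at `spike_rate`
#' per minute. The native sampling rate (15,277 Hz by default) exercises
#' the resampler.
#'
#' @param subj A [simulate_subject()] result.
#' @param protocol Protocol (defaults to the subject's own).
#' @param keep_components Attach the clean and noise components as
#'   attributes (for SNR oracles in tests).
#' @return An [audio_recording()] at the subject's audio rate.
#' @export
synthesize_audio <- function(subj, protocol = subj$protocol,
                             keep_components = FALSE) {
  rate <- subj$rate
  dur <- protocol_duration(protocol)
  n <- ceiling(dur * rate)
  tb <- .breath_schedule(subj)
  periods <- c(diff(tb), 60 / true_rr(subj, tb[length(tb)]))
  ve <- .gas_model(subj, tb)$ve

  set.seed(subj$seed + 1299709L)
  power <- subj$coupling * ve * exp(rnorm(length(tb), 0, subj$cv_coupling))
  env <- numeric(n)
  burst <- function(t_on, t_off, amp) {
    i0 <- max(1L, floor(t_on * rate) + 1L)
    i1 <- min(n, floor(t_off * rate))
    if (i1 <= i0) return(invisible())
    m <- i1 - i0 + 1L
    w <- rep(1, m)
    r <- max(2L, round(0.2 * m))
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(r) / r)
    w[seq_len(r)] <- ramp
    w[m + 1L - seq_len(r)] <- ramp
    env[i0:i1] <<- env[i0:i1] + amp * w / sqrt(mean(w^2))
  }
  for (k in seq_along(tb)) {
    p <- periods[k]
    a <- sqrt(power[k])
    burst(tb[k] + 0.02 * p, tb[k] + 0.40 * p, a)
    burst(tb[k] + 0.52 * p, tb[k] + 0.82 * p, 0.75 * a)
  }

  sos <- butter_sos(4, 100, min(3000, 0.45 * rate), rate)
  carrier <- sosfilt_cpp(sos, rnorm(n))
  carrier <- carrier / stats::sd(carrier)
  clean <- carrier * env

  active <- env > 0
  burst_power <- mean(clean[active]^2)
  noise <- if (is.finite(subj$snr_db)) {
    amb <- sosfilt_cpp(sos, rnorm(n))
    amb * sqrt(burst_power / 10^(subj$snr_db / 10)) / stats::sd(amb)
  } else {
    numeric(n)
  }

  x <- clean + noise
  n_spike <- rpois(1, subj$spike_rate * dur / 60)
  if (n_spike > 0) {
    amp_spike <- 5 * max(env)
    for (tc in runif(n_spike, 0, dur)) {
      i0 <- max(1L, floor(tc * rate))
      len <- round(0.03 * rate)
      i1 <- min(n, i0 + len - 1L)
      x[i0:i1] <- x[i0:i1] + amp_spike * sin(pi * seq_len(i1 - i0 + 1L) / (i1 - i0 + 1L))
    }
  }

  peak <- max(abs(x))
  scale <- if (peak > 0.99) 0.99 / peak else 1
  rec <- audio_recording(x * scale, rate, 0)
  if (keep_components) {
    attr(rec, "clean") <- clean * scale
    attr(rec, "noise") <- noise * scale
  }
  rec
}

#' Idealized feature series straight from the generator
#'
#' The per-breath features the audio pipeline would recover under perfect
#' segmentation: intensity proportional to programmed ventilation with the
#' configured coupling scatter, energy = intensity x breath period, rate
#' from the actual (jittered) breath schedule — assembled onto the uniform
#' grid by [build_feature_series()]. This is the fast path for regression
#' experiments, where rendering and re-analysing audio adds cost but no
#' information.
#'
#' @param subj A [simulate_subject()] result.
#' @param protocol Protocol (defaults to the subject's own).
#' @param grid_step,smooth_breaths Passed to [build_feature_series()].
#' @return A `feature_series`.
#' @export
simulate_feature_series <- function(subj, protocol = subj$protocol,
                                    grid_step = 1, smooth_breaths = 5) {
  tb <- .breath_schedule(subj)
  periods <- c(diff(tb), 60 / true_rr(subj, tb[length(tb)]))
  ve <- .gas_model(subj, tb)$ve
  set.seed(subj$seed + 15485863L)
  intensity <- subj$coupling * ve * exp(rnorm(length(tb), 0, subj$cv_coupling))
  pb <- data.frame(time = tb + periods / 2,
                   energy = intensity * periods,
                   intensity = intensity,
                   duration = periods,
                   onset = tb)
  build_feature_series(pb, protocol, grid_step = grid_step,
                       smooth_breaths = smooth_breaths)
}

#' Simulate a cohort
#'
#' Independent subjects whose seeds derive from the master seed; each
#' record holds the subject, its protocol, its gas exchange and (when
#' `cfg$include_audio`) its audio.
#'
#' @param cfg A [simulation_config()].
#' @return A list of records `list(subject, protocol, gas, audio)`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  seeds <- sample.int(2^20, cfg$n)
  lapply(seq_len(cfg$n), function(i) {
    subj <- simulate_subject(cfg, seed = seeds[i])
    gas <- simulate_gas_exchange(subj)
    audio <- if (cfg$include_audio) synthesize_audio(subj) else NULL
    list(subject = subj, protocol = subj$protocol, gas = gas, audio = audio)
  })
}
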