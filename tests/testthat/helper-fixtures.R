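# Shared fixtures. Heavy end-to-end results are computed once per test run
# and cached in an environment so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

# internal biquad-cascade filter, used to build band-limited fixtures
sosfilt_cpp <- cpetsound:::sosfilt_cpp

# A burst train at 6000 Hz: band-limited noise bursts of `burst_s` seconds
# every `period_s` seconds, with raised-cosine ramps. Returns the recording
# plus the clean/noise decomposition when ambient noise is requested.
make_burst_train <- function(duration = 60, period_s = 4, burst_s = 1,
                             rate = 6000, amp = 0.3, snr_db = Inf,
                             seed = 1, band = c(250, 2000)) {
  set.seed(seed)
  n <- duration * rate
  env <- numeric(n)
  onsets <- seq(0, duration - burst_s, by = period_s)
  m <- round(burst_s * rate)
  r <- round(0.15 * m)
  w <- rep(1, m)
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(r) / r)
  w[seq_len(r)] <- ramp
  w[m + 1 - seq_len(r)] <- ramp
  for (on in onsets) {
    i0 <- floor(on * rate) + 1
    env[i0:(i0 + m - 1)] <- amp * w
  }
  sos <- butter_sos(4, band[1], band[2], rate)
  carrier <- sosfilt_cpp(sos, rnorm(n))
  carrier <- carrier / sd(carrier)
  clean <- carrier * env
  noise <- if (is.finite(snr_db)) {
    nz <- sosfilt_cpp(sos, rnorm(n))
    nz / sd(nz) * sqrt(mean(clean[env > 0]^2) / 10^(snr_db / 10))
  } else {
    numeric(n)
  }
  list(rec = audio_recording(clean + noise, rate),
       clean = clean, noise = noise, onsets = onsets, n_bursts = length(onsets))
}

# Small synthetic subject with overridable fields (e.g. constant breathing
# rate or zero noise) for targeted closed-loop tests.
make_subject <- function(seed = 7, cfg = simulation_config(n = 1, seed = 1),
                         ...) {
  subj <- simulate_subject(cfg, seed = seed)
  dots <- list(...)
  for (nm in names(dots)) subj[[nm]] <- dots[[nm]]
  subj
}

# Noiseless variant of a subject (gas and coupling noise off).
make_noiseless_subject <- function(seed = 7, ...) {
  make_subject(seed = seed, cv_breath = 0, cv_channel = 0, cv_coupling = 0,
               snr_db = Inf, spike_rate = 0, ...)
}

# The default 24-subject cohort evaluated end to end through the audio
# pipeline (the expensive shared fixture; cached).
default_cohort_eval <- function() {
  if (is.null(.fixture_cache$cohort_eval)) {
    cfg <- simulation_config(n = 24, seed = 1)
    cohort <- simulate_cohort(cfg)
    .fixture_cache$cohort_eval <- evaluate_cohort_at(cohort)
  }
  .fixture_cache$cohort_eval
}

# Independent brute-force two-segment fit (the oracle): plain lm() at every
# candidate knot, no shared code with fit_two_segment.
brute_force_knee <- function(times, values, margin = 3L) {
  n <- length(times)
  best <- NULL
  for (i in seq(margin + 1L, n - margin)) {
    tc <- times[i]
    d <- data.frame(y = values,
                    b1 = pmin(times - tc, 0),
                    b2 = pmax(times - tc, 0))
    f <- lm(y ~ b1 + b2, data = d)
    sse <- sum(residuals(f)^2)
    if (is.null(best) || sse < best$sse * (1 - 1e-12)) {
      best <- list(tc = tc, sse = sse, coef = coef(f))
    }
  }
  best
}
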