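piecewise <- function(t, knee, s1, s2, y0 = 1) {
  y0 + s1 * pmin(t - knee, 0) + s2 * pmax(t - knee, 0)
}

test_that("the two-segment fit recovers a noiseless knee exactly", {
  t <- seq(180, 700, by = 10)
  y <- piecewise(t, 340, 0.01, 0.05)
  fit <- fit_two_segment(t, y)
  expect_equal(fit$breakpoint, 340)
  expect_lt(fit$sse2, 1e-18)
  expect_equal(fit$slope_before, 0.01, tolerance = 1e-9)
  expect_equal(fit$slope_after, 0.05, tolerance = 1e-9)
  expect_gt(fit$improvement, 0.5)

  line <- fit_two_segment(t, 2 + 0.03 * t)
  expect_lt(line$improvement, 0.05)

  expect_error(fit_two_segment(1:5, 1:5), "at least 8")
})

test_that("the fit equals an independent brute-force search, also under noise", {
  t <- seq(180, 700, by = 1)
  clean <- piecewise(t, 340, 0.01, 0.05)
  knee_err <- vapply(314:318, function(seed) {
    set.seed(seed)
    y <- clean + rnorm(length(t), 0, 0.1 * diff(range(clean)))
    fit <- fit_two_segment(t, y)
    oracle <- brute_force_knee(t, y)
    expect_equal(fit$breakpoint, oracle$tc)
    expect_equal(fit$sse2, oracle$sse, tolerance = 1e-9)
    abs(fit$breakpoint - 340)
  }, numeric(1))
  expect_lte(median(knee_err), 20)

  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(20:120, 1)
    tt <- sort(runif(n, 0, 100))
    tt <- tt[c(TRUE, diff(tt) > 1e-6)]
    yy <- piecewise(tt, runif(1, 30, 70), runif(1, -1, 1), runif(1, -1, 1)) +
      rnorm(length(tt), 0, 0.5)
    f <- fit_two_segment(tt, yy)
    o <- brute_force_knee(tt, yy)
    expect_equal(f$breakpoint, o$tc)
    expect_equal(f$sse2, o$sse, tolerance = 1e-8)
  }
})

test_that("acoustic detection applies the validity rules", {
  subj <- make_noiseless_subject(seed = 5)
  fs <- simulate_feature_series(subj)
  det <- detect_at_acoustic(fs, "intensity", subj$protocol)
  expect_true(det$detected)
  expect_lt(abs(det$time - subj$at_time), 20)
  expect_equal(det$stage, stage_at_time(subj$protocol, subj$at_time)$stage)

  # affine rescaling of the feature leaves the detection unchanged
  fs2 <- fs
  fs2$intensity <- 3.7 * fs2$intensity + 11
  det2 <- detect_at_acoustic(fs2, "intensity", subj$protocol)
  expect_equal(det2$time, det$time)

  # a pure line is not a detection (improvement rule)
  fs3 <- fs
  fs3$intensity <- 1 + 0.01 * fs3$time
  expect_false(detect_at_acoustic(fs3, "intensity", subj$protocol)$detected)

  # a decelerating trace is not a detection (rising-slope rule)
  fs4 <- fs
  fs4$intensity <- piecewise(fs4$time, subj$at_time, 0.05, 0.01)
  expect_false(detect_at_acoustic(fs4, "intensity", subj$protocol)$detected)

  expect_error(detect_at_acoustic(fs[, c("time", "stage", "missing")],
                                  "intensity", subj$protocol), "missing")
})

test_that("the ventilatory-equivalents nadir sits at the threshold", {
  # noiseless subject doctored to the canonical 340-s threshold: the nadir
  # of VE/VO2 falls on the breath nearest 340 s while VE/VCO2 still falls
  subj <- make_noiseless_subject(seed = 9)
  subj$at_time <- 340
  subj$vo2_at <- cpetsound:::.vo2_model(subj, 340)
  gas <- simulate_gas_exchange(subj)
  ref <- reference_at_ventilatory(gas, subj$protocol, subj$profile$weight)
  expect_true(ref$determined)
  breath_gap <- max(diff(gas$breaths$time))
  expect_lt(abs(ref$time - 340), breath_gap)

  eq <- ventilatory_equivalents(gas)
  near <- which(abs(eq$time - 340) < 30)
  expect_lt(coef(lm(eq$ve_vco2[near] ~ eq$time[near]))[2], 0)
})

test_that("a boundary nadir is rejected as undetermined", {
  # strictly decreasing VE/VO2: nadir would be the last exercise sample
  tb <- seq(0, 780, by = 3)[-1]
  vo2 <- 500 + 2 * tb
  ve <- 20 + 0.001 * vo2          # VE/VO2 strictly decreasing
  gas <- gas_exchange_series(tb, vo2, 0.9 * vo2, ve)
  proto <- build_protocol(25, 5)
  ref <- reference_at_ventilatory(gas, proto, 60)
  expect_false(ref$determined)
})

test_that("the reference threshold is accurate at default noise", {
  errs <- vapply(101:110, function(seed) {
    subj <- make_subject(seed = seed)
    gas <- simulate_gas_exchange(subj)
    ref <- reference_at_ventilatory(gas, subj$protocol, subj$profile$weight)
    abs(ref$time - subj$at_time)
  }, numeric(1))
  expect_lte(median(errs), 10)
})

test_that("agreement scoring mirrors the stage and 20-s rules", {
  proto <- build_protocol(25, 5)
  gas <- simulate_gas_exchange(make_noiseless_subject(seed = 3))
  mk_est <- function(t) structure(list(detected = TRUE, time = t,
                                       stage = stage_at_time(proto, t)$stage,
                                       workload = NA, feature = "intensity"),
                                  class = "at_detection")
  ref <- structure(list(determined = TRUE, time = 340,
                        stage = stage_at_time(proto, 340)$stage,
                        workload = NA, vo2_at_kg = NA),
                   class = "reference_at")
  a1 <- evaluate_at_agreement(mk_est(350), ref, gas, proto)
  expect_true(a1$same_stage && a1$within_20s)
  expect_equal(a1$time_diff, 10)

  a2 <- evaluate_at_agreement(mk_est(380), ref, gas, proto)
  expect_equal(a2$time_diff, 40)
  expect_false(a2$within_20s)

  und <- structure(list(detected = FALSE, time = NA_real_,
                        stage = NA_integer_, workload = NA_real_,
                        feature = "intensity"),
                   class = "at_detection")
  a3 <- evaluate_at_agreement(und, ref, gas, proto)
  expect_false(a3$same_stage)
  expect_true(is.na(a3$time_diff))
})

test_that("the V-slope cross-check lands near the programmed threshold", {
  subj <- make_noiseless_subject(seed = 13)
  gas <- simulate_gas_exchange(subj)
  vs <- vslope_at(gas, subj$protocol)
  expect_lt(abs(vs$vo2_at - subj$vo2_at) / subj$vo2_at, 0.05)
  expect_lt(abs(vs$time - subj$at_time), 30)
})
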