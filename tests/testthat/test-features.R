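make_cycles <- function(onset, offset) {
  structure(data.frame(onset = onset, offset = offset,
                       duration = offset - onset,
                       n_phases = 2L),
            class = c("breath_cycles", "data.frame"))
}

test_that("per-breath energy and intensity follow their closed forms", {
  rec <- audio_recording(rep(0.1, 6000 * 3), 6000)
  pb <- per_breath_features(rec, make_cycles(0, 1))
  expect_equal(pb$energy, 60, tolerance = 1e-3)
  expect_equal(pb$intensity, 60, tolerance = 1e-3)
  expect_equal(pb$time, 0.5)

  pb2 <- per_breath_features(rec, make_cycles(0, 2))
  expect_equal(pb2$energy, 120, tolerance = 1e-3)
  expect_equal(pb2$intensity, 60, tolerance = 1e-3)

  expect_error(per_breath_features(rec, make_cycles(1, 1)), "zero-duration")
  expect_error(per_breath_features(rec, make_cycles(2, 9)), "beyond")
})

test_that("pipeline intensity rises monotonically with programmed ventilation", {
  subj <- make_subject(seed = 21, n_stages = 3)
  subj$protocol <- build_protocol(increment_w = subj$protocol$increment_w,
                                  n_stages = 3, warmup_s = 60, stage_s = 60,
                                  recovery_s = 30)
  subj$at_time <- 150
  subj$vo2_at <- cpetsound:::.vo2_model(subj, 150)
  audio <- synthesize_audio(subj)
  clean <- preprocess_audio(audio)
  cyc <- detect_breath_cycles(compute_envelope(clean))
  pb <- per_breath_features(clean, cyc)
  ve <- cpetsound:::.gas_model(subj, pb$time)$ve
  expect_gt(cor(pb$intensity, ve, method = "spearman"), 0.9)
})

test_that("grid series reproduces constant rates and the ventilation identity", {
  onsets <- seq(0, 600, by = 5)
  pb <- data.frame(time = onsets + 2, energy = 10, intensity = 5,
                   duration = 4, onset = onsets)
  proto <- build_protocol(25, 4)
  fs <- build_feature_series(pb, proto)
  expect_true(all(abs(fs$rr - 12) < 1e-9))
  expect_equal(fs$acoustic_ventilation, fs$rr * fs$intensity)

  pb$intensity <- 5
  pb$energy <- 20
  fs2 <- build_feature_series(pb, proto)
  expect_true(all(abs(fs2$acoustic_ventilation - 60) < 1e-9))
})

test_that("features scale quadratically with gain while rates are unchanged", {
  bt <- make_burst_train(duration = 50, period_s = 3, seed = 31, snr_db = 15)
  cyc <- detect_breath_cycles(compute_envelope(bt$rec))
  pb1 <- per_breath_features(bt$rec, cyc)
  rec_c <- audio_recording(bt$rec$samples * 3, bt$rec$rate)
  pb2 <- per_breath_features(rec_c, detect_breath_cycles(compute_envelope(rec_c)))
  expect_equal(pb2$energy, 9 * pb1$energy, tolerance = 1e-9)
  expect_equal(pb2$intensity, 9 * pb1$intensity, tolerance = 1e-9)

  proto <- build_protocol(25, 4, warmup_s = 0, recovery_s = 0)
  fs1 <- build_feature_series(pb1, proto)
  fs2 <- build_feature_series(pb2, proto)
  expect_equal(fs1$rr, fs2$rr)
})

test_that("stage labels partition the grid exactly as the protocol does", {
  proto <- build_protocol(20, 5)
  subj <- make_subject(seed = 41)
  fs <- simulate_feature_series(subj)
  b <- subj$protocol$boundaries
  for (k in seq_len(nrow(b))) {
    sel <- fs$time >= b$start[k] & fs$time < b$end[k]
    expect_true(all(fs$stage[sel] == b$stage[k]))
  }
  expect_false(any(is.na(fs$stage)))
})

test_that("grid respiratory rate tracks a programmed ramp within 1.2 bpm", {
  err <- vapply(c(51, 52, 53), function(seed) {
    subj <- make_subject(seed = seed, rr_start = 12, rr_end = 30)
    fs <- simulate_feature_series(subj)
    ex <- fs$stage > 0 & !fs$missing
    mean(abs(fs$rr[ex] - true_rr(subj, fs$time[ex])))
  }, numeric(1))
  expect_lt(mean(err), 1.2)
})

test_that("feature CSV round-trips through the exchange format", {
  subj <- make_subject(seed = 61)
  fs <- simulate_feature_series(subj)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fs, path)
  back <- read_features_csv(path)
  expect_equal(back$intensity, fs$intensity, tolerance = 1e-9)
  expect_equal(back$rr, fs$rr, tolerance = 1e-9)
  expect_equal(back$stage, fs$stage)
})
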