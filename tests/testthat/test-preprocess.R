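rate <- 15277

test_that("SOS band-pass design matches the reference Butterworth response", {
  sos <- butter_sos(4, 100, 3000, rate)
  bf <- signal::butter(4, c(100, 3000) / (rate / 2), type = "pass")
  f <- c(20, 50, 100, 500, 1000, 2500, 3000, 5000)
  z <- exp(1i * 2 * pi * f / rate)
  h_sos <- vapply(z, function(zz) {
    abs(prod((sos[, 1] * zz^2 + sos[, 2] * zz + sos[, 3]) /
               (zz^2 + sos[, 5] * zz + sos[, 6])))
  }, numeric(1))
  h_ba <- vapply(z, function(zz) {
    abs(sum(bf$b * zz^(0:-8)) / sum(bf$a * zz^(0:-8)))
  }, numeric(1))
  expect_equal(h_sos, h_ba, tolerance = 1e-8)
})

test_that("band-pass keeps passband tones and rejects out-of-band content", {
  t <- seq(0, 1, by = 1 / rate)
  rms <- function(x) sqrt(mean(x^2))

  tone <- audio_recording(sin(2 * pi * 1000 * t), rate)
  out <- bandpass_filter(tone)
  expect_equal(rms(out$samples) / rms(tone$samples), 1, tolerance = 0.01)
  expect_length(out$samples, length(tone$samples))

  hum <- audio_recording(sin(2 * pi * 50 * t), rate)
  atten <- 20 * log10(rms(bandpass_filter(hum)$samples) / rms(hum$samples))
  expect_lt(atten, -40)

  set.seed(1)
  wn <- audio_recording(rnorm(rate * 2), rate)
  fw <- bandpass_filter(wn)
  p <- Mod(fft(fw$samples))^2
  freq <- (seq_along(p) - 1) / length(p) * rate
  inband <- freq >= 100 & freq <= 3000 | freq >= rate - 3000 & freq <= rate - 100
  expect_gt(sum(p[inband]) / sum(p), 0.95)

  expect_error(bandpass_filter(wn, high = 8000), "Nyquist")
})

test_that("zero-phase filtering introduces no group delay", {
  # a short pulse keeps its centre of mass after filtering
  t <- seq(0, 1, by = 1 / rate)
  x <- exp(-((t - 0.5) / 0.01)^2) * sin(2 * pi * 800 * t)
  y <- bandpass_filter(audio_recording(x, rate))$samples
  com <- function(v) sum(seq_along(v) * v^2) / sum(v^2)
  expect_lt(abs(com(x) - com(y)) / rate, 0.001)
})

test_that("resampling preserves length arithmetic and tone amplitude", {
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  rec <- audio_recording(sin(2 * pi * 1000 * t), rate)
  out <- resample_audio(rec, 6000)
  expect_identical(length(out$samples), 6000L)
  expect_identical(out$rate, 6000)
  # FFT peak of the resampled tone: still 1 kHz at full amplitude
  p <- Mod(fft(out$samples * (0.5 - 0.5 * cos(2 * pi * seq_len(6000) / 6000))))
  fpk <- (which.max(p[1:3000]) - 1) / 6000 * 6000
  expect_equal(fpk, 1000, tolerance = 1)
  expect_equal(sqrt(mean(out$samples^2)), sqrt(0.5), tolerance = 0.01)

  z <- resample_audio(audio_recording(numeric(rate), rate), 6000)
  expect_true(all(z$samples == 0))
  expect_error(resample_audio(out, 12000), "upsampling")
})

test_that("denoiser leaves clean bursts intact but strips stationary noise", {
  clean <- make_burst_train(duration = 40, snr_db = Inf, seed = 2)
  out <- denoise_ambient(clean$rec)
  expect_length(out$samples, length(clean$rec$samples))
  dist <- sqrt(mean((out$samples - clean$clean)^2)) / sqrt(mean(clean$clean^2))
  expect_lt(dist, 0.10)

  noisy <- make_burst_train(duration = 40, snr_db = 0, seed = 3)
  den <- denoise_ambient(noisy$rec)
  err_in <- noisy$rec$samples - noisy$clean
  err_out <- den$samples - noisy$clean
  snr <- function(err) 10 * log10(sum(noisy$clean^2) / sum(err^2))
  expect_gt(snr(err_out) - snr(err_in), 6)

  set.seed(4)
  sos <- butter_sos(4, 100, 2500, 6000)
  pure <- audio_recording(sosfilt_cpp(sos, rnorm(6000 * 20)) * 0.05, 6000)
  den2 <- denoise_ambient(pure)
  expect_lt(sqrt(mean(den2$samples^2)), 0.5 * sqrt(mean(pure$samples^2)))

  expect_error(denoise_ambient(audio_recording(rnorm(100), 6000)),
               "longer than")
})

test_that("denoiser never increases per-frame energy", {
  noisy <- make_burst_train(duration = 30, snr_db = 5, seed = 5)
  out <- denoise_ambient(noisy$rec)
  fr <- function(x) {
    starts <- seq(1, length(x) - 299, by = 300)
    vapply(starts, function(s) sum(x[s:(s + 299)]^2), numeric(1))
  }
  e_in <- fr(noisy$rec$samples)
  e_out <- fr(out$samples)
  expect_true(all(e_out <= e_in * (1 + 1e-6) + 1e-12))
})

test_that("spike removal interpolates impulses and passes clean signals", {
  # breath-like duty cycle (~60%): the rolling median tracks the burst level
  burst <- make_burst_train(duration = 30, period_s = 4, burst_s = 2.5,
                            snr_db = 20, seed = 6)
  x <- burst$rec$samples
  i_spk <- 6000 * 10 + seq_len(120)  # 20 ms impulse at t = 10 s
  x[i_spk] <- 10 * max(abs(x))
  spiked <- audio_recording(x, 6000)
  out <- remove_spikes(spiked)
  changed <- which(out$samples != spiked$samples)
  expect_lt(length(changed) / length(x), 0.02)
  expect_true(all(abs(changed - mean(i_spk)) < 6000))  # only near the spike
  expect_lt(max(abs(out$samples[i_spk])), max(abs(x[i_spk])) / 2)

  smooth <- audio_recording(sin(2 * pi * 3 * seq(0, 10, by = 1 / 6000)) * 0.3, 6000)
  expect_identical(remove_spikes(smooth)$samples, smooth$samples)

  zero <- audio_recording(numeric(6000), 6000)
  expect_identical(remove_spikes(zero)$samples, zero$samples)

  expect_error(remove_spikes(zero, window = 1e-4), "3 samples")
})

test_that("the chain is idempotent in band content", {
  # carrier concentrated where tracheal sounds live (300-1200 Hz), well
  # inside the 100-3000 Hz analysis band
  noisy <- make_burst_train(duration = 30, period_s = 4, burst_s = 2.5,
                            snr_db = 10, seed = 8, rate = 15277,
                            band = c(300, 1200))
  once <- preprocess_audio(noisy$rec, target_rate = 15277)
  again <- bandpass_filter(once, low = 100, high = 3000)
  rms <- function(r) sqrt(mean(r$samples^2))
  expect_equal(rms(again) / rms(once), 1, tolerance = 1e-3)
})
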