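toy_gas <- function(times, vo2) {
  gas_exchange_series(times, vo2, 0.9 * vo2, 0.028 * vo2)
}

test_that("oxygen-uptake smoothing takes bin means and fills gaps", {
  g1 <- toy_gas(seq(0.5, 99.5, by = 2.5), rep(2000, 40))
  sv <- smooth_vo2(g1)
  expect_true(all(abs(sv$vo2 - 2000) < 1e-9))

  g2 <- toy_gas(c(10.2, 10.7), c(1800, 2200))
  expect_equal(smooth_vo2(g2)$vo2, 2000)

  # linear ramp: bin means equal an independently computed aggregate
  set.seed(12)
  tb <- sort(runif(200, 0, 120))
  vo2 <- 500 + 10 * tb
  g3 <- toy_gas(tb, vo2)
  sv3 <- smooth_vo2(g3)
  t0 <- floor(min(tb))
  oracle <- tapply(vo2, floor(tb - t0), mean)
  idx <- as.integer(names(oracle)) + 1L
  expect_equal(sv3$vo2[idx], as.numeric(oracle), tolerance = 1e-9)
})

test_that("the reference peak is the best 10-s window mean per kilogram", {
  g <- toy_gas(seq(0.5, 119.5, by = 1), rep(2100, 120))
  expect_equal(reference_vo2peak(g, 70), 30)

  vo2 <- rep(1000, 120)
  vo2[61:70] <- 3000    # one elevated 10-s window
  g2 <- toy_gas(seq(0.5, 119.5, by = 1), vo2)
  expect_equal(reference_vo2peak(g2, 60), 50)

  # zero-noise simulator: the programmed peak is recovered exactly
  subj <- make_noiseless_subject(seed = 17)
  gas <- simulate_gas_exchange(subj)
  expect_equal(reference_vo2peak(gas, subj$profile$weight), subj$vo2peak_kg,
               tolerance = 1e-9)
})

test_that("design matrices expose exactly the configured predictors", {
  subj <- make_subject(seed = 23)
  fs <- simulate_feature_series(subj)
  gas <- simulate_gas_exchange(subj)
  w <- subj$profile$weight

  d1 <- build_design_matrix(fs, gas, regression_config(feature_set = "respiratory"), w)
  expect_identical(setdiff(names(d1), c("vo2_kg", "time")),
                   c("rr", "energy", "acoustic_ventilation"))

  d2 <- build_design_matrix(fs, gas, regression_config(feature_set = "resp_hr_wl"),
                            w, subj$protocol)
  expect_identical(setdiff(names(d2), c("vo2_kg", "time")),
                   c("rr", "energy", "acoustic_ventilation", "hr", "workload"))

  d3 <- build_design_matrix(fs, gas, regression_config(feature_set = "all_acoustic"), w)
  expect_identical(setdiff(names(d3), c("vo2_kg", "time")),
                   c("energy", "intensity", "rr", "acoustic_ventilation"))

  gas_nohr <- gas
  gas_nohr$hr <- data.frame(time = numeric(0), hr = numeric(0))
  expect_error(build_design_matrix(fs, gas_nohr,
                                   regression_config(feature_set = "resp_hr_wl"),
                                   w, subj$protocol),
               "heart rate")
})

test_that("backends recover linear targets and are seed-deterministic", {
  set.seed(5)
  n <- 200
  d <- data.frame(rr = runif(n, 10, 40), energy = runif(n, 1, 5),
                  acoustic_ventilation = runif(n, 10, 100))
  d$vo2_kg <- 3 + 0.5 * d$rr + 2 * d$energy - 0.1 * d$acoustic_ventilation
  d$time <- seq_len(n)
  tr <- d[1:150, ]; te <- d[151:200, ]

  cfg_lm <- regression_config(model = "lm")
  expect_equal(fit_predict(tr, te, cfg_lm), te$vo2_kg, tolerance = 1e-9)

  dc <- d; dc$vo2_kg <- 7
  expect_equal(fit_predict(dc[1:150, ], dc[151:200, ], cfg_lm),
               rep(7, 50), tolerance = 1e-9)
  cfg_rf <- regression_config(model = "rf", ntree = 50, seed = 42)
  expect_equal(suppressWarnings(fit_predict(dc[1:150, ], dc[151:200, ], cfg_rf)),
               rep(7, 50), tolerance = 1e-9)

  p1 <- fit_predict(tr, te, cfg_rf)
  p2 <- fit_predict(tr, te, cfg_rf)
  expect_identical(p1, p2)

  sing <- d; sing$energy <- sing$rr * 2
  expect_error(fit_predict(sing[1:150, ], sing[151:200, ], cfg_lm), "singular")
})

test_that("subject-specific folds are contiguous blocks, each predicted once", {
  set.seed(6)
  n <- 100
  d <- data.frame(rr = runif(n, 10, 40), energy = runif(n, 1, 5),
                  acoustic_ventilation = runif(n, 10, 100))
  d$vo2_kg <- 5 + 0.3 * d$rr + d$energy
  d$time <- seq_len(n)
  cfg <- regression_config(model = "lm", folds = 5)
  cv <- cv_subject_specific(d, cfg)
  expect_identical(as.integer(table(cv$fold)), rep(20L, 5))
  expect_true(all(diff(cv$fold) >= 0))      # contiguous blocks in time order
  expect_length(cv$predicted, n)
  expect_equal(cv$predicted, d$vo2_kg, tolerance = 1e-9)  # linear oracle
  expect_equal(cv$predicted_peak, max(d$vo2_kg), tolerance = 1e-9)

  cv2 <- cv_subject_specific(d[1:10, ], regression_config(model = "lm", folds = 2))
  expect_identical(as.integer(table(cv2$fold)), c(5L, 5L))
  expect_error(cv_subject_specific(d[1:3, ], regression_config(folds = 5)),
               "fewer rows")
})

test_that("cross-validation schemes cannot leak their own rows", {
  # fold-level: the held-out block's distinctive constant target cannot be
  # reproduced by a model trained only on the other blocks
  set.seed(7)
  n <- 50
  d <- data.frame(rr = rnorm(n), energy = rnorm(n),
                  acoustic_ventilation = rnorm(n))
  d$time <- seq_len(n)
  d$vo2_kg <- rep(c(10, 20, 30, 40, 50), each = 10)
  cv <- cv_subject_specific(d, regression_config(model = "lm", folds = 5))
  for (f in 1:5) {
    expect_gt(mean(abs(cv$predicted[cv$fold == f] - unique(d$vo2_kg)[f])), 1)
  }

  # subject-level: a held-out subject's constant target is invisible in
  # training, so its prediction must miss it
  mk <- function(const, seed) {
    set.seed(seed)
    data.frame(rr = rnorm(30), energy = rnorm(30),
               acoustic_ventilation = rnorm(30),
               vo2_kg = const, time = 1:30)
  }
  cohort <- list(a = mk(10, 1), b = mk(25, 2), c = mk(40, 3))
  loso <- cv_loso(cohort, regression_config(model = "lm"))
  expect_length(loso, 3)
  expect_gt(mean(abs(loso$a$predicted - 10)), 3)
  expect_gt(mean(abs(loso$c$predicted - 40)), 3)
  expect_error(cv_loso(cohort[1], regression_config()), "at least 2")
})

test_that("leave-one-subject-out is order invariant and oracle-consistent", {
  set.seed(8)
  mk <- function(seed) {
    set.seed(seed)
    d <- data.frame(rr = runif(60, 10, 40), energy = runif(60, 1, 5),
                    acoustic_ventilation = runif(60, 10, 100))
    d$vo2_kg <- 4 + 0.4 * d$rr + 1.5 * d$energy + 0.05 * d$acoustic_ventilation
    d$time <- 1:60
    d
  }
  cohort <- list(s1 = mk(11), s2 = mk(12), s3 = mk(13))
  cfg <- regression_config(model = "lm")
  l1 <- cv_loso(cohort, cfg)
  l2 <- cv_loso(rev(cohort), cfg)
  expect_equal(l1$s2$predicted, l2$s2$predicted)
  # same generating law for all subjects: peaks recovered, and the peak is
  # the maximum of the reassembled trace (appending lower-valued rows after
  # the peak cannot change it)
  for (s in names(cohort)) {
    expect_equal(l1[[s]]$predicted_peak, max(cohort[[s]]$vo2_kg),
                 tolerance = 1e-6)
    expect_equal(l1[[s]]$predicted_peak, max(l1[[s]]$predicted))
  }
})
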