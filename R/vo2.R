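# Oxygen-uptake regression from acoustic features: subject-specific 5-fold
# and subject-independent leave-one-subject-out validation.

#' Smooth breath-by-breath oxygen uptake onto a uniform grid
#'
#' Bin means on a `step`-second grid (abrupt breath-level artifacts are
#' averaged out); empty bins are filled by linear interpolation.
#'
#' @param gas A [gas_exchange_series()].
#' @param step Grid step, seconds.
#' @return Data frame with `time` (bin centres) and `vo2` (mL/min).
#' @export
smooth_vo2 <- function(gas, step = 1) {
  b <- gas$breaths
  if (nrow(b) == 0L) stop("empty gas-exchange series")
  t0 <- floor(min(b$time) / step) * step
  bin <- floor((b$time - t0) / step)
  n_bins <- max(bin) + 1L
  means <- rep(NA_real_, n_bins)
  agg <- tapply(b$vo2, bin, mean)
  means[as.integer(names(agg)) + 1L] <- agg
  centres <- t0 + (seq_len(n_bins) - 0.5) * step
  if (anyNA(means)) {
    ok <- which(!is.na(means))
    means <- stats::approx(centres[ok], means[ok], xout = centres, rule = 2)$y
  }
  data.frame(time = centres, vo2 = means)
}

#' Reference peak oxygen uptake
#'
#' Breath-by-breath VO2 averaged in consecutive (non-overlapping) `window`-s
#' windows; the peak window mean normalized by body mass is the reference
#' peak.
#'
#' @param gas A [gas_exchange_series()] spanning at least one window.
#' @param body_mass Kilograms.
#' @param window Averaging window, seconds.
#' @return mL/kg/min.
#' @export
reference_vo2peak <- function(gas, body_mass, window = 10) {
  b <- gas$breaths
  if (diff(range(b$time)) < window) stop("gas series shorter than one averaging window")
  bin <- floor((b$time - min(b$time)) / window)
  max(tapply(b$vo2, bin, mean)) / body_mass
}

#' Regression configuration
#'
#' @param model `"rf"` (regression random forest) or `"lm"` (multiple
#'   linear regression by ordinary least squares).
#' @param feature_set Predictor set: `"respiratory"` (respiratory rate,
#'   sound energy, acoustic ventilation = RR x intensity),
#'   `"resp_hr_wl"` (respiratory plus heart rate and workload) or
#'   `"all_acoustic"` (the four acoustic features).
#' @param ntree Trees in the forest.
#' @param seed RNG seed used for every stochastic step; recorded in all
#'   outputs.
#' @param folds Fold count for subject-specific cross-validation (>= 2).
#' @param fold_scheme `"blocks"` for contiguous time blocks (default;
#'   avoids leaking temporal autocorrelation) or `"random"` for seeded
#'   random row assignment.
#' @return A list of class `regression_config`.
#' @export
regression_config <- function(model = c("rf", "lm"),
                              feature_set = c("respiratory", "resp_hr_wl",
                                              "all_acoustic"),
                              ntree = 500, seed = 1, folds = 5,
                              fold_scheme = c("blocks", "random")) {
  if (folds < 2) stop("'folds' must be at least 2")
  structure(list(model = match.arg(model), feature_set = match.arg(feature_set),
                 ntree = ntree, seed = seed, folds = folds,
                 fold_scheme = match.arg(fold_scheme)),
            class = "regression_config")
}

.feature_columns <- function(feature_set) {
  switch(feature_set,
         respiratory = c("rr", "energy", "acoustic_ventilation"),
         resp_hr_wl = c("rr", "energy", "acoustic_ventilation", "hr", "workload"),
         all_acoustic = c("energy", "intensity", "rr", "acoustic_ventilation"))
}

#' Assemble the regression design matrix
#'
#' Predictors per the configured feature set, time-aligned on the feature
#' grid; the target is the 1-s smoothed oxygen uptake normalized by body
#' mass. Heart rate is interpolated from its own time base; workload comes
#' from the protocol stage at each grid time. Rows with any missing value
#' are dropped (their count is kept in attribute `"n_dropped"`).
#'
#' @param features A `feature_series`.
#' @param gas The matching [gas_exchange_series()].
#' @param cfg A [regression_config()].
#' @param body_mass Kilograms.
#' @param protocol `protocol_spec`; required for the `resp_hr_wl` set.
#' @return Data frame with the predictor columns, `vo2_kg` (target) and
#'   `time`.
#' @export
build_design_matrix <- function(features, gas, cfg, body_mass, protocol = NULL) {
  cols <- .feature_columns(cfg$feature_set)
  d <- data.frame(time = features$time)
  for (cc in setdiff(cols, c("hr", "workload"))) d[[cc]] <- features[[cc]]
  if ("hr" %in% cols) {
    if (nrow(gas$hr) == 0L) stop("heart rate required by feature set but absent")
    d$hr <- stats::approx(gas$hr$time, gas$hr$hr, xout = d$time, rule = 2)$y
  }
  if ("workload" %in% cols) {
    if (is.null(protocol)) stop("protocol required for the workload predictor")
    sw <- stage_at_time(protocol, d$time)
    d$workload <- ifelse(is.na(sw$workload), 0, sw$workload)
  }
  sv <- smooth_vo2(gas)
  lo <- max(min(sv$time), min(d$time))
  hi <- min(max(sv$time), max(d$time))
  if (hi <= lo) stop("no temporal overlap between features and gas exchange")
  d$vo2_kg <- stats::approx(sv$time, sv$vo2, xout = d$time)$y / body_mass
  keep <- stats::complete.cases(d) & d$time >= lo & d$time <= hi
  out <- d[keep, c(cols, "vo2_kg", "time")]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Fit on training rows, predict test rows
#'
#' Deterministic given `cfg$seed`. The linear backend refuses singular
#' designs with a diagnostic; the forest backend is a regression random
#' forest.
#'
#' @param train,test Design-matrix data frames sharing the same columns.
#' @param cfg A [regression_config()].
#' @return Numeric predictions for `test` rows.
#' @export
fit_predict <- function(train, test, cfg) {
  stopifnot(nrow(train) > 0L)
  cols <- setdiff(names(train), c("vo2_kg", "time"))
  if (!identical(cols, setdiff(names(test), c("vo2_kg", "time")))) {
    stop("train and test schemas differ")
  }
  x_tr <- as.matrix(train[cols])
  x_te <- as.matrix(test[cols])
  if (cfg$model == "lm") {
    X <- cbind(1, x_tr)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      stop("singular linear design (rank ", qx$rank, " < ", ncol(X),
           "); condition estimate ", format(kappa(X)))
    }
    beta <- qr.coef(qx, train$vo2_kg)
    as.numeric(cbind(1, x_te) %*% beta)
  } else {
    set.seed(cfg$seed)
    rf <- randomForest::randomForest(x = x_tr, y = train$vo2_kg,
                                     ntree = cfg$ntree)
    as.numeric(predict(rf, x_te))
  }
}

.fold_assignment <- function(n, cfg) {
  if (cfg$fold_scheme == "blocks") {
    sort(rep_len(seq_len(cfg$folds), n))
  } else {
    set.seed(cfg$seed)
    sample(rep_len(seq_len(cfg$folds), n))
  }
}

#' Subject-specific cross-validated oxygen-uptake prediction
#'
#' The subject's rows (time-ordered) are split into `cfg$folds` contiguous
#' blocks; each block is predicted by a model trained on the remaining
#' blocks, the trace is reassembled in time order and its maximum is the
#' predicted peak.
#'
#' @param data Design matrix for one subject (see [build_design_matrix()]).
#' @param cfg A [regression_config()].
#' @param ref_peak Optional reference peak (mL/kg/min) to carry along.
#' @return A list of class `vo2_prediction`: `times`, `predicted`,
#'   `predicted_peak`, `reference_peak`, `scheme`, `seed`, `fold` (the fold
#'   id of every row).
#' @export
cv_subject_specific <- function(data, cfg = regression_config(), ref_peak = NA_real_) {
  data <- data[order(data$time), ]
  n <- nrow(data)
  if (n < cfg$folds) stop("fewer rows than folds")
  fold <- .fold_assignment(n, cfg)
  pred <- numeric(n)
  for (f in seq_len(cfg$folds)) {
    hold <- fold == f
    pred[hold] <- fit_predict(data[!hold, , drop = FALSE],
                              data[hold, , drop = FALSE], cfg)
  }
  structure(list(times = data$time, predicted = pred,
                 predicted_peak = max(pred),
                 reference_peak = ref_peak,
                 scheme = "subject-specific", seed = cfg$seed, fold = fold),
            class = "vo2_prediction")
}

#' Leave-one-subject-out oxygen-uptake prediction
#'
#' Each subject's full trace is predicted by a model trained on the pooled
#' rows of all other subjects; per-subject predicted peaks feed the
#' agreement analysis. The result for a subject does not depend on the
#' order of the input list.
#'
#' @param cohort Named list of per-subject design matrices.
#' @param cfg A [regression_config()].
#' @param ref_peaks Optional named numeric vector of reference peaks.
#' @return Named list of `vo2_prediction` objects (`scheme` =
#'   `"subject-independent"`).
#' @export
cv_loso <- function(cohort, cfg = regression_config(), ref_peaks = NULL) {
  if (length(cohort) < 2L) stop("leave-one-subject-out needs at least 2 subjects")
  ids <- names(cohort)
  if (is.null(ids)) ids <- as.character(seq_along(cohort))
  out <- vector("list", length(cohort))
  names(out) <- ids
  for (i in seq_along(cohort)) {
    train <- do.call(rbind, cohort[-i])
    test <- cohort[[i]]
    pred <- fit_predict(train, test, cfg)
    out[[i]] <- structure(list(times = test$time, predicted = pred,
                               predicted_peak = max(pred),
                               reference_peak = if (is.null(ref_peaks)) NA_real_
                                                else unname(ref_peaks[ids[i]]),
                               scheme = "subject-independent",
                               seed = cfg$seed, fold = NULL),
                          class = "vo2_prediction")
  }
  out
}
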