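# Breath-by-breath gas-exchange container and the ventilatory equivalents.

#' Breath-by-breath gas-exchange series
#'
#' @param time Breath times, seconds (strictly increasing).
#' @param vo2,vco2 Oxygen uptake / carbon-dioxide output, mL/min (> 0).
#' @param ve Minute ventilation, L/min (> 0).
#' @param vt Tidal volume, L (optional).
#' @param hr Heart rate, beats/min (optional; may have its own time base
#'   `hr_time`).
#' @param hr_time Times of the heart-rate samples, seconds; defaults to the
#'   breath times.
#' @return A list of class `gas_exchange` with data frames `breaths` and
#'   `hr`.
#' @export
gas_exchange_series <- function(time, vo2, vco2, ve, vt = NULL,
                                hr = NULL, hr_time = NULL) {
  stopifnot(length(time) == length(vo2), length(vo2) == length(vco2),
            length(vco2) == length(ve))
  if (is.unsorted(time, strictly = TRUE)) stop("breath times must be strictly increasing")
  if (any(vo2 <= 0) || any(vco2 <= 0) || any(ve <= 0)) {
    stop("vo2, vco2 and ve must be positive")
  }
  breaths <- data.frame(time = time, vo2 = vo2, vco2 = vco2, ve = ve,
                        vt = if (is.null(vt)) NA_real_ else vt)
  hr_df <- if (is.null(hr)) {
    data.frame(time = numeric(0), hr = numeric(0))
  } else {
    data.frame(time = if (is.null(hr_time)) time else hr_time, hr = hr)
  }
  structure(list(breaths = breaths, hr = hr_df), class = "gas_exchange")
}

#' Ventilatory equivalents
#'
#' Recomputed from the stored channels on every call (never cached):
#' `VE/VO2 = ve / (vo2/1000)` and `VE/VCO2 = ve / (vco2/1000)`, both
#' dimensionless.
#'
#' @param gas A [gas_exchange_series()].
#' @return Data frame with `time`, `ve_vo2`, `ve_vco2`.
#' @export
ventilatory_equivalents <- function(gas) {
  b <- gas$breaths
  data.frame(time = b$time,
             ve_vo2 = b$ve / (b$vo2 / 1000),
             ve_vco2 = b$ve / (b$vco2 / 1000))
}

#' Write / read gas exchange as CSV
#'
#' Columns: `time_s, vo2_ml_min, vco2_ml_min, ve_l_min, vt_l, hr_bpm`
#' (heart rate interpolated onto breath times when it has its own base).
#'
#' @param gas A `gas_exchange`.
#' @param path File path.
#' @export
write_gas_csv <- function(gas, path) {
  b <- gas$breaths
  hr <- if (nrow(gas$hr) > 0L) {
    stats::approx(gas$hr$time, gas$hr$hr, xout = b$time, rule = 2)$y
  } else {
    NA_real_
  }
  utils::write.csv(data.frame(time_s = b$time, vo2_ml_min = b$vo2,
                              vco2_ml_min = b$vco2, ve_l_min = b$ve,
                              vt_l = b$vt, hr_bpm = hr),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gas_csv
#' @export
read_gas_csv <- function(path) {
  d <- utils::read.csv(path)
  gas_exchange_series(d$time_s, d$vo2_ml_min, d$vco2_ml_min, d$ve_l_min,
                      vt = d$vt_l,
                      hr = if (all(is.na(d$hr_bpm))) NULL else d$hr_bpm)
}

# 10-s-averaged VO2 value at a given time (window centred on t), mL/min
.vo2_10s_at <- function(gas, t, window = 10) {
  b <- gas$breaths
  sel <- b$time >= t - window / 2 & b$time <= t + window / 2
  if (!any(sel)) return(NA_real_)
  mean(b$vo2[sel])
}
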