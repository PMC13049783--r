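# Respiratory-phase detection from the log-power envelope.

#' Short-time log-power envelope
#'
#' @param rec An [audio_recording()].
#' @param frame Frame length, seconds.
#' @param hop Frame hop, seconds (`0 < hop <= frame`).
#' @param eps Power floor added before the log, keeps silence finite.
#' @return An `envelope_series`: list with `times` (frame centers on the
#'   protocol clock, seconds), `values` (dB, `10*log10(mean(x^2) + eps)`),
#'   `frame` and `hop`.
#' @export
compute_envelope <- function(rec, frame = 0.05, hop = 0.025, eps = 1e-12) {
  stopifnot(inherits(rec, "audio_recording"))
  n <- length(rec$samples)
  m <- round(frame * rec$rate)
  h <- max(1L, round(hop * rec$rate))
  if (m < 1L || h < 1L || h > m) stop("need 0 < hop <= frame")
  if (m > n) stop("frame longer than the recording")
  starts <- seq(1L, n - m + 1L, by = h)
  cs <- cumsum(c(0, rec$samples^2))
  p <- (cs[starts + m] - cs[starts]) / m
  structure(list(times = rec$t0 + (starts - 1 + (m - 1) / 2) / rec$rate,
                 values = 10 * log10(p + eps),
                 frame = m / rec$rate, hop = h / rec$rate),
            class = "envelope_series")
}

#' Segmentation thresholds for breath-phase detection
#'
#' The baseline is an adaptive rolling percentile of the envelope, so the
#' detector tracks the rising sound floor across exercise stages and is
#' invariant to global gain.
#'
#' @param baseline_window Rolling window for the baseline percentile, seconds.
#' @param baseline_quantile Percentile defining the baseline (fraction).
#' @param high_db,low_db Hysteresis margins above the baseline: a phase opens
#'   above `baseline + high_db` and closes below `baseline + low_db`.
#' @param min_phase Minimum phase duration, seconds.
#' @param min_gap Phases separated by less than this many seconds are merged.
#' @param min_breath Minimum accepted breath-cycle duration, seconds.
#' @return A list of class `breath_params`.
#' @export
breath_params <- function(baseline_window = 15, baseline_quantile = 0.20,
                          high_db = 6, low_db = 3,
                          min_phase = 0.15, min_gap = 0.10, min_breath = 1.0) {
  stopifnot(baseline_window > 0, baseline_quantile > 0, baseline_quantile < 1,
            high_db > low_db, min_phase > 0, min_gap >= 0)
  structure(list(baseline_window = baseline_window,
                 baseline_quantile = baseline_quantile,
                 high_db = high_db, low_db = low_db,
                 min_phase = min_phase, min_gap = min_gap,
                 min_breath = min_breath),
            class = "breath_params")
}

# rolling percentile evaluated on a coarse grid, then linearly interpolated
.rolling_quantile <- function(times, values, window, prob, grid_step = 1) {
  t0 <- times[1]
  t1 <- times[length(times)]
  grid <- seq(t0, t1, by = grid_step)
  if (length(grid) < 2L) grid <- c(t0, t1)
  half <- window / 2
  qs <- vapply(grid, function(g) {
    sel <- values[times >= g - half & times <= g + half]
    stats::quantile(sel, probs = prob, names = FALSE)
  }, numeric(1))
  stats::approx(grid, qs, xout = times, rule = 2)$y
}

#' Detect breath cycles from an envelope
#'
#' Dual-threshold hysteresis on the log envelope against an adaptive
#' rolling-percentile baseline. Sound phases shorter than `min_phase` are
#' discarded and phases separated by gaps shorter than `min_gap` are merged.
#' Consecutive phases are then paired (two sound bursts per respiratory
#' cycle); each cycle runs from the onset of its first phase to the onset of
#' the next cycle (the last cycle ends at its final phase offset). A
#' trailing unpaired phase is dropped.
#'
#' @param env An `envelope_series` from [compute_envelope()]; must cover at
#'   least 10 s.
#' @param params A [breath_params()].
#' @return A data frame of class `breath_cycles` with columns `onset`,
#'   `offset`, `duration` (seconds, protocol clock) and `n_phases`; the
#'   detected phases are attached as attribute `"phases"` (data frame with
#'   `onset`, `offset`). Zero rows when nothing is detected.
#' @export
detect_breath_cycles <- function(env, params = breath_params()) {
  stopifnot(inherits(env, "envelope_series"))
  if (diff(range(env$times)) < 10) stop("envelope must cover at least 10 s")
  v <- env$values
  base <- .rolling_quantile(env$times, v, params$baseline_window,
                            params$baseline_quantile)
  runs <- hysteresis_runs_cpp(v, base + params$high_db, base + params$low_db)
  empty <- structure(data.frame(onset = numeric(0), offset = numeric(0),
                                duration = numeric(0), n_phases = integer(0)),
                     phases = data.frame(onset = numeric(0), offset = numeric(0)),
                     class = c("breath_cycles", "data.frame"))
  if (nrow(runs) == 0L) return(empty)

  onset <- env$times[runs[, 1]] - env$hop / 2
  offset <- env$times[runs[, 2]] + env$hop / 2

  # merge phases separated by short gaps
  if (nrow(runs) > 1L) {
    keep_on <- onset[1]
    m_on <- c(); m_off <- c()
    cur_off <- offset[1]
    for (j in 2:length(onset)) {
      if (onset[j] - cur_off < params$min_gap) {
        cur_off <- offset[j]
      } else {
        m_on <- c(m_on, keep_on); m_off <- c(m_off, cur_off)
        keep_on <- onset[j]; cur_off <- offset[j]
      }
    }
    m_on <- c(m_on, keep_on); m_off <- c(m_off, cur_off)
    onset <- m_on; offset <- m_off
  }

  long_enough <- (offset - onset) >= params$min_phase
  onset <- onset[long_enough]; offset <- offset[long_enough]
  if (length(onset) < 2L) return(empty)

  phases <- data.frame(onset = onset, offset = offset)

  n_pairs <- length(onset) %/% 2L
  first <- seq(1L, by = 2L, length.out = n_pairs)
  cyc_on <- onset[first]
  cyc_off <- c(if (n_pairs > 1L) cyc_on[-1L], offset[first[n_pairs] + 1L])
  np <- rep(2L, n_pairs)

  dur <- cyc_off - cyc_on
  ok <- dur >= params$min_breath
  out <- data.frame(onset = cyc_on[ok], offset = cyc_off[ok],
                    duration = dur[ok], n_phases = np[ok])
  structure(out, phases = phases, class = c("breath_cycles", "data.frame"))
}
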