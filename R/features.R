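# Per-breath acoustic features and the uniform-grid feature series.

#' Per-breath acoustic features
#'
#' For each breath cycle: sound energy (sum of squared amplitude over the
#' cycle), sound intensity (energy divided by cycle duration, i.e. average
#' acoustic power) and duration. Both are unitless because the acquisition
#' gain is uncalibrated. The time stamp is the cycle midpoint.
#'
#' @param rec The cleaned [audio_recording()].
#' @param cycles A `breath_cycles` data frame from [detect_breath_cycles()].
#' @return Data frame with `time`, `energy`, `intensity`, `duration`,
#'   `onset`.
#' @export
per_breath_features <- function(rec, cycles) {
  stopifnot(inherits(rec, "audio_recording"))
  if (nrow(cycles) == 0L) {
    return(data.frame(time = numeric(0), energy = numeric(0),
                      intensity = numeric(0), duration = numeric(0),
                      onset = numeric(0)))
  }
  if (any(cycles$offset <= cycles$onset)) stop("zero-duration breath cycle")
  t_end <- rec$t0 + length(rec$samples) / rec$rate
  if (any(cycles$onset < rec$t0 - 1e-9) || any(cycles$offset > t_end + 1e-9)) {
    stop("breath cycles extend beyond the recording span")
  }
  cs <- cumsum(c(0, rec$samples^2))
  n <- length(rec$samples)
  i0 <- pmax(1L, pmin(n, floor((cycles$onset - rec$t0) * rec$rate) + 1L))
  i1 <- pmax(i0, pmin(n, ceiling((cycles$offset - rec$t0) * rec$rate)))
  energy <- cs[i1 + 1L] - cs[i0]
  duration <- cycles$offset - cycles$onset
  data.frame(time = (cycles$onset + cycles$offset) / 2,
             energy = energy,
             intensity = energy / duration,
             duration = duration,
             onset = cycles$onset)
}

#' Build the uniform-grid feature series
#'
#' Instantaneous respiratory rate comes from onset-to-onset intervals of
#' successive breaths; energy, intensity and rate are median-smoothed over
#' `smooth_breaths` breaths and linearly interpolated onto a uniform grid.
#' Acoustic ventilation is computed pointwise on the grid as
#' `rr * intensity` (the acoustic analogue of minute ventilation =
#' respiratory rate x average acoustic power). Grid points farther than
#' `gap_tol` seconds from any breath are flagged missing (`NA` channels),
#' never silently zero. Each grid point carries its protocol stage label.
#'
#' @param pb Per-breath table from [per_breath_features()].
#' @param protocol A [build_protocol()] spec.
#' @param grid_step Grid spacing, seconds.
#' @param smooth_breaths Width (breaths) of the centered rolling median.
#' @param gap_tol Maximum distance to the nearest breath midpoint, seconds.
#' @return A data frame of class `feature_series` with columns `time`,
#'   `energy`, `intensity`, `rr`, `acoustic_ventilation`, `stage`,
#'   `missing`.
#' @export
build_feature_series <- function(pb, protocol, grid_step = 1,
                                 smooth_breaths = 5, gap_tol = 5) {
  if (nrow(pb) == 0L) stop("no breaths to build a feature series from")
  if (grid_step <= 0) stop("'grid_step' must be positive")
  pb <- pb[order(pb$time), ]

  intervals <- diff(pb$onset)
  rr <- 60 / intervals
  rr <- c(rr, rr[length(rr)])  # last breath inherits the preceding interval

  sm <- function(x) {
    k <- min(smooth_breaths, length(x))
    if (k %% 2L == 0L) k <- k - 1L
    if (k < 3L) return(x)
    stats::runmed(x, k, endrule = "median")
  }
  energy_s <- sm(pb$energy)
  intensity_s <- sm(pb$intensity)
  rr_s <- sm(rr)

  proto_end <- protocol_duration(protocol)
  lo <- max(min(pb$time), 0)
  hi <- min(max(pb$time), proto_end * (1 - 1e-12))
  if (hi <= lo) stop("feature grid is empty: no overlap between breaths and protocol")
  grid <- seq(ceiling(lo / grid_step) * grid_step, hi, by = grid_step)

  interp <- function(y) stats::approx(pb$time, y, xout = grid, rule = 2)$y
  energy_g <- interp(energy_s)
  intensity_g <- interp(intensity_s)
  rr_g <- interp(rr_s)

  nearest <- vapply(grid, function(g) min(abs(pb$time - g)), numeric(1))
  miss <- nearest > gap_tol
  energy_g[miss] <- NA_real_
  intensity_g[miss] <- NA_real_
  rr_g[miss] <- NA_real_

  out <- data.frame(time = grid,
                    energy = energy_g,
                    intensity = intensity_g,
                    rr = rr_g,
                    acoustic_ventilation = rr_g * intensity_g,
                    stage = stage_at_time(protocol, grid)$stage,
                    missing = miss)
  structure(out, class = c("feature_series", "data.frame"))
}

#' Write / read a feature series as CSV
#' @param fs A `feature_series`.
#' @param path File path.
#' @export
write_features_csv <- function(fs, path) {
  utils::write.csv(
    data.frame(time_s = fs$time, energy = fs$energy, intensity = fs$intensity,
               rr_bpm = fs$rr, acoustic_ventilation = fs$acoustic_ventilation,
               stage = fs$stage),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(data.frame(time = d$time_s, energy = d$energy,
                       intensity = d$intensity, rr = d$rr_bpm,
                       acoustic_ventilation = d$acoustic_ventilation,
                       stage = d$stage,
                       missing = !is.finite(d$rr_bpm)),
            class = c("feature_series", "data.frame"))
}
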