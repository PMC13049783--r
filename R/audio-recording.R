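#' Audio recording container
#'
#' A tracheal-sound recording: a numeric sample vector, its sampling rate and
#' the time offset of the first sample relative to the exercise-protocol
#' clock. Amplitudes are dimensionless (the acquisition gain is uncalibrated)
#' and are kept in `[-1, 1]`.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample on the protocol clock, seconds.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, rate, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("'rate' must be a single positive number")
  }
  structure(list(samples = samples, rate = rate, t0 = t0),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording: %d samples @ %.6g Hz, %.2f s, t0 = %.2f s>\n",
              length(x$samples), x$rate, rec_duration(x), x$t0))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `audio_recording`.
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$rate

#' Sample times of a recording on the protocol clock
#' @param rec An `audio_recording`.
#' @return Numeric vector, seconds.
#' @export
rec_times <- function(rec) rec$t0 + (seq_along(rec$samples) - 1) / rec$rate

#' Load a mono WAV file as an audio recording
#'
#' Multi-channel files are reduced to the per-frame channel mean with a
#' warning. Samples are rescaled into `[-1, 1]` only when the file contains
#' values outside that range (float files written by other software); values
#' already in range are left untouched so that files produced by
#' [save_audio()] round-trip exactly.
#'
#' @param path Path to a PCM-16 or float-32 WAV file.
#' @param t0 Time of the first sample on the protocol clock, seconds.
#' @return An [audio_recording()].
#' @export
load_audio <- function(path, t0 = 0) {
  wav <- read_wav(path)
  x <- wav$samples
  if (is.matrix(x)) {
    warning("multi-channel WAV reduced to channel mean: ", path)
    x <- rowMeans(x)
  }
  peak <- max(abs(x), 0)
  if (peak > 1) x <- x / peak
  audio_recording(x, wav$rate, t0 = t0)
}

#' Save an audio recording to WAV
#'
#' @param rec An `audio_recording`.
#' @param path Output path.
#' @param format `"pcm"` (16-bit) or `"float"` (32-bit).
#' @export
save_audio <- function(rec, path, format = c("pcm", "float")) {
  write_wav(rec$samples, rec$rate, path, format = match.arg(format))
}
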