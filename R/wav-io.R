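# Minimal RIFF/WAVE reader and writer (16-bit PCM and 32-bit IEEE float).
# Only the "fmt " and "data" chunks are interpreted; other chunks are skipped.
# Samples are exchanged as doubles in [-1, 1]; the 16-bit codec uses the
# symmetric scale x = i / 32767 so that write -> read round-trips exactly.

.wav_u16 <- function(raw2) {
  readBin(raw2, "integer", n = 1L, size = 2L, signed = FALSE, endian = "little")
}
.wav_u32 <- function(raw4) {
  lo <- .wav_u16(raw4[1:2])
  hi <- .wav_u16(raw4[3:4])
  lo + hi * 65536
}

#' Read a RIFF/WAVE file
#'
#' Supports uncompressed 16-bit integer PCM and 32-bit IEEE-float WAV files,
#' mono or multi-channel (interleaved).
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector for mono, or a matrix with
#'   one column per channel), `rate` (sampling frequency, Hz), `bits`
#'   (bit depth) and `format` (`"pcm"` or `"float"`).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "raw", 4L) # overall size, unused
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- .wav_u32(readBin(con, "raw", 4L))
    body <- readBin(con, "raw", size)
    if (length(body) < size) stop("truncated WAV chunk '", id, "' in ", path)
    if (size %% 2L == 1L) readBin(con, "raw", 1L) # pad byte
    if (identical(id, "fmt ")) fmt <- body
    if (identical(id, "data")) data_raw <- body
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw)) stop("WAV file has no data chunk: ", path)

  audio_format <- .wav_u16(fmt[1:2])
  n_channels <- .wav_u16(fmt[3:4])
  rate <- .wav_u32(fmt[5:8])
  bits <- .wav_u16(fmt[15:16])

  if (audio_format == 1L && bits == 16L) {
    x <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little") / 32767
    format <- "pcm"
  } else if (audio_format == 3L && bits == 32L) {
    x <- readBin(data_raw, "numeric", n = length(data_raw) %/% 4L,
                 size = 4L, endian = "little")
    format <- "float"
  } else {
    stop("unsupported WAV encoding (format tag ", audio_format,
         ", ", bits, " bits); only 16-bit PCM and 32-bit float are handled")
  }

  if (n_channels > 1L) {
    x <- t(matrix(x, nrow = n_channels))
  }
  list(samples = x, rate = rate, bits = bits, format = format)
}

#' Write a RIFF/WAVE file
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel; values are expected in `[-1, 1]` and are clamped.
#' @param rate Sampling frequency in Hz.
#' @param path Output path.
#' @param format `"pcm"` for 16-bit integer PCM or `"float"` for 32-bit
#'   IEEE float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, format = c("pcm", "float")) {
  format <- match.arg(format)
  x <- if (is.matrix(samples)) as.numeric(t(samples)) else as.numeric(samples)
  n_channels <- if (is.matrix(samples)) ncol(samples) else 1L
  x <- pmax(pmin(x, 1), -1)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  bits <- if (format == "pcm") 16L else 32L
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per
  block_align <- n_channels * bytes_per

  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_u32 <- function(v) {
    v <- as.numeric(v)
    w_u16(v %% 65536)
    w_u16(v %/% 65536)
  }
  writeChar("RIFF", con, 4L, eos = NULL)
  w_u32(36 + data_size)
  writeChar("WAVE", con, 4L, eos = NULL)
  writeChar("fmt ", con, 4L, eos = NULL)
  w_u32(16)
  w_u16(if (format == "pcm") 1L else 3L)
  w_u16(n_channels)
  w_u32(rate)
  w_u32(rate * block_align)
  w_u16(block_align)
  w_u16(bits)
  writeChar("data", con, 4L, eos = NULL)
  w_u32(data_size)
  if (format == "pcm") {
    writeBin(as.integer(round(x * 32767)), con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}
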