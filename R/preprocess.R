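# Audio preprocessing: band-pass filtering, resampling, ambient-noise
# suppression and motion-spike removal.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' Classic pole placement on the analog prototype, band-pass transformation
#' and bilinear mapping. Returning second-order sections (rather than a
#' single transfer-function polynomial) keeps the cascade numerically stable
#' at narrow normalized bands.
#'
#' @param n Prototype order (the band-pass filter has `2n` poles).
#' @param low,high Band edges in Hz.
#' @param rate Sampling frequency in Hz.
#' @return A `k x 6` matrix of sections `(b0, b1, b2, 1, a1, a2)`.
#' @export
butter_sos <- function(n = 4L, low, high, rate) {
  if (low <= 0 || high <= low || high >= rate / 2) {
    stop("band edges must satisfy 0 < low < high < rate/2")
  }
  c2 <- 2 * rate
  w1 <- c2 * tan(pi * low / rate)
  w2 <- c2 * tan(pi * high / rate)
  bw <- w2 - w1
  w0sq <- w1 * w2

  # analog prototype poles (unit Butterworth circle, left half-plane)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  # band-pass transform: each prototype pole p yields the roots of
  # s^2 - p*bw*s + w0^2
  s_poles <- c()
  for (p in proto) {
    disc <- sqrt(as.complex((p * bw)^2 - 4 * w0sq))
    s_poles <- c(s_poles, (p * bw + disc) / 2, (p * bw - disc) / 2)
  }
  z_poles <- (c2 + s_poles) / (c2 - s_poles)

  # group digital poles into conjugate pairs
  pos <- z_poles[Im(z_poles) >= 0]
  pos <- pos[order(Re(pos), Im(pos))]
  neg <- z_poles[Im(z_poles) < 0]
  neg <- neg[order(Re(Conj(neg)), Im(Conj(neg)))]
  if (length(pos) != length(neg)) {
    # real poles (possible for odd prototypes): pair real poles together
    re_p <- sort(Re(z_poles[abs(Im(z_poles)) < 1e-9]))
    cx_p <- z_poles[Im(z_poles) > 1e-9]
    pairs <- lapply(cx_p, function(z) c(z, Conj(z)))
    if (length(re_p) %% 2L != 0L) stop("internal error: unpaired real pole")
    if (length(re_p) > 0) {
      pairs <- c(pairs, lapply(seq(1, length(re_p), by = 2),
                               function(i) as.complex(re_p[c(i, i + 1)])))
    }
  } else {
    pairs <- lapply(seq_along(pos), function(i) c(pos[i], Conj(pos[i])))
  }

  sos <- t(vapply(pairs, function(zz) {
    a1 <- -Re(zz[1] + zz[2])
    a2 <- Re(zz[1] * zz[2])
    c(1, 0, -1, 1, a1, a2)
  }, numeric(6)))

  # normalize to unit gain at the (analog) center frequency
  omega0 <- 2 * atan(sqrt(w0sq) / c2)
  z <- exp(1i * omega0)
  h <- prod(vapply(seq_len(nrow(sos)), function(j) {
    abs((sos[j, 1] * z^2 + sos[j, 2] * z + sos[j, 3]) /
          (z^2 + sos[j, 5] * z + sos[j, 6]))
  }, numeric(1)))
  g <- (1 / h)^(1 / nrow(sos))
  sos[, 1:3] <- sos[, 1:3] * g
  sos
}

# Zero-phase (forward-backward) application of an SOS cascade with
# reflected-edge padding to suppress end transients.
.zero_phase_sosfilt <- function(sos, x) {
  n <- length(x)
  npad <- min(n - 1L, 2000L)
  if (npad > 0L) {
    xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  } else {
    xp <- x
  }
  y <- sosfilt_cpp(sos, xp)
  y <- rev(sosfilt_cpp(sos, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Band-pass filter a recording (zero-phase)
#'
#' Order-4 Butterworth applied forward and backward, so the passband gain is
#' the squared magnitude response and the phase is exactly zero: breath-onset
#' timing is preserved. Defaults cover the typical spectral range of normal
#' tracheal respiratory sounds.
#'
#' @param rec An [audio_recording()].
#' @param low,high Band edges in Hz (must satisfy `0 < low < high < rate/2`).
#' @param order Butterworth prototype order.
#' @return A filtered `audio_recording` with the same length and rate.
#' @export
bandpass_filter <- function(rec, low = 100, high = 3000, order = 4L) {
  stopifnot(inherits(rec, "audio_recording"))
  if (high >= rec$rate / 2) {
    stop("'high' must be below the Nyquist frequency (", rec$rate / 2, " Hz)")
  }
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  sos <- butter_sos(order, low, high, rec$rate)
  audio_recording(.zero_phase_sosfilt(sos, rec$samples), rec$rate, rec$t0)
}

#' Resample a band-limited recording to a lower rate
#'
#' Cubic-spline interpolation onto the new sample grid. The signal must
#' already be band-limited below `target_rate / 2` (the band-pass stage
#' guarantees this in the standard chain); no additional anti-alias filter is
#' applied.
#'
#' @param rec An [audio_recording()].
#' @param target_rate New sampling frequency in Hz; must not exceed the
#'   current rate (upsampling is not supported).
#' @return An `audio_recording` at `target_rate` with
#'   `round(n * target_rate / rate)` samples.
#' @export
resample_audio <- function(rec, target_rate = 6000) {
  stopifnot(inherits(rec, "audio_recording"))
  if (target_rate > rec$rate) stop("upsampling not supported (target_rate > rate)")
  if (target_rate == rec$rate) return(rec)
  n <- length(rec$samples)
  new_n <- round(n * target_rate / rec$rate)
  xi <- (seq_len(new_n) - 1) * (rec$rate / target_rate) + 1
  y <- stats::spline(seq_len(n), rec$samples, xout = xi, method = "fmm")$y
  audio_recording(y, target_rate, rec$t0)
}

#' Parameters of the ambient-noise suppressor
#'
#' @param frame STFT frame length, seconds.
#' @param overlap Frame overlap as a fraction in `[0, 1)`.
#' @param noise_quantile Quantile of per-frequency spectral power (over time)
#'   used to estimate the stationary noise floor; must be in `(0, 1)`.
#' @param floor_gain Minimum linear gain applied to any time-frequency cell,
#'   in `(0, 1]`; prevents musical-noise artifacts from full suppression.
#' @param oversubtraction Multiplier on the estimated noise power before
#'   subtraction; values around 2 counter the heavy-tailed fluctuation of
#'   short-time noise power (classic spectral-subtraction practice).
#' @return A list of class `denoise_config`.
#' @export
denoise_config <- function(frame = 0.05, overlap = 0.75,
                           noise_quantile = 0.10, floor_gain = 0.05,
                           oversubtraction = 2) {
  if (frame <= 0) stop("'frame' must be positive")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  if (noise_quantile <= 0 || noise_quantile >= 1) stop("'noise_quantile' must be in (0, 1)")
  if (floor_gain <= 0 || floor_gain > 1) stop("'floor_gain' must be in (0, 1]")
  if (oversubtraction <= 0) stop("'oversubtraction' must be positive")
  structure(list(frame = frame, overlap = overlap,
                 noise_quantile = noise_quantile, floor_gain = floor_gain,
                 oversubtraction = oversubtraction),
            class = "denoise_config")
}

#' Suppress stationary ambient noise
#'
#' Short-time spectral suppression: the recording is analysed with a Hann
#' windowed STFT, a per-frequency noise floor is estimated from a low
#' quantile of spectral power over time (rescaled to the noise mean under an
#' exponential-power model, so quiet gaps calibrate the floor), cell gains
#' `g = sqrt(max(1 - N/P, floor_gain^2))` are applied, and the signal is
#' rebuilt by weighted overlap-add. Gains never exceed one, so no
#' time-frequency cell ever gains energy.
#'
#' @param rec An [audio_recording()] (typically filtered and resampled).
#' @param cfg A [denoise_config()].
#' @return A denoised `audio_recording` of identical length and rate.
#' @export
denoise_ambient <- function(rec, cfg = denoise_config()) {
  stopifnot(inherits(rec, "audio_recording"))
  x0 <- rec$samples
  n <- length(x0)
  m <- round(cfg$frame * rec$rate)
  if (m > n) stop("denoise frame is longer than the recording")
  hop <- max(1L, round(m * (1 - cfg$overlap)))

  # reflect one frame at each end so every retained sample has full window
  # coverage (otherwise the overlap-add normalization is ill-conditioned at
  # the edges once gains modify the spectra)
  x <- c(x0[m:1], x0, x0[n:(n - m + 1L)])
  np <- length(x)
  n_frames <- as.integer(ceiling((np - m) / hop)) + 1L
  total <- (n_frames - 1L) * hop + m
  if (total > np) x <- c(x, numeric(total - np))

  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / m)
  starts <- seq(0L, by = hop, length.out = n_frames)
  idx <- outer(seq_len(m), starts, "+")
  X <- matrix(x[idx], nrow = m) * w
  rm(idx)
  S <- stats::mvfft(X)
  rm(X)
  P <- Re(S * Conj(S))

  # noise floor per frequency from a low quantile over time; a subsample of
  # frames is ample for the estimate on long recordings
  stride <- max(1L, n_frames %/% 10000L)
  q <- apply(P[, seq(1L, n_frames, by = stride), drop = FALSE], 1L,
             stats::quantile, probs = cfg$noise_quantile, names = FALSE)
  noise_mean <- q / (-log(1 - cfg$noise_quantile))
  gain2 <- pmax(1 - cfg$oversubtraction * noise_mean / pmax(P, .Machine$double.xmin),
                cfg$floor_gain^2)
  rm(P)
  S <- S * sqrt(gain2)
  rm(gain2)

  frames <- Re(stats::mvfft(S, inverse = TRUE)) / m
  rm(S)
  frames <- frames * w
  y <- numeric(total)
  norm <- numeric(total)
  wsq <- w * w
  if (m %% hop == 0L) {
    # hop divides the frame: chunk c of every frame lands contiguously
    chunks <- m %/% hop
    ones <- matrix(1, nrow = 1L, ncol = n_frames)
    for (ch in seq_len(chunks) - 1L) {
      rows <- ch * hop + seq_len(hop)
      rng <- (ch * hop + 1L):(ch * hop + hop * n_frames)
      y[rng] <- y[rng] + as.vector(frames[rows, , drop = FALSE])
      norm[rng] <- norm[rng] + as.vector(wsq[rows] %o% ones[1L, ])
    }
  } else {
    for (j in seq_len(n_frames)) {
      rng <- (starts[j] + 1L):(starts[j] + m)
      y[rng] <- y[rng] + frames[, j]
      norm[rng] <- norm[rng] + wsq
    }
  }
  y <- y / pmax(norm, .Machine$double.eps)
  audio_recording(y[m + seq_len(n)], rec$rate, rec$t0)
}

#' Remove sparse high-amplitude motion spikes
#'
#' The short-time RMS envelope is compared with a rolling robust threshold
#' (rolling median plus `k` times the rolling median absolute deviation,
#' both over `stat_window` seconds). Samples in excess runs, dilated by half
#' an envelope window, are replaced by linear interpolation across the run;
#' all other samples pass through untouched.
#'
#' @param rec An [audio_recording()].
#' @param window Envelope window in seconds (must span at least 3 samples).
#' @param k Threshold multiplier on the rolling MAD.
#' @param stat_window Window for the rolling median/MAD, seconds.
#' @param mad_floor Lower bound on the rolling MAD as a fraction of the
#'   rolling median. The envelope of breath audio is locally near-constant
#'   inside a burst, which can drive the raw MAD to zero and make the
#'   threshold degenerate; the floor keeps the threshold a safe multiple of
#'   the local level while still catching an impulse several times it.
#' @return An `audio_recording` with flagged runs interpolated.
#' @export
remove_spikes <- function(rec, window = 0.1, k = 5, stat_window = 2,
                          mad_floor = 0.3) {
  stopifnot(inherits(rec, "audio_recording"))
  if (window <= 0 || k <= 0) stop("'window' and 'k' must be positive")
  x <- rec$samples
  n <- length(x)
  m <- round(window * rec$rate)
  if (m < 3L) stop("'window' must span at least 3 samples")

  h <- m %/% 2L
  cs <- cumsum(c(0, x^2))
  iu <- pmin(seq_len(n) + h, n)
  il <- pmax(seq_len(n) - h, 0L)
  env <- sqrt((cs[iu + 1L] - cs[il + 1L]) / (iu - il))

  # robust rolling statistics on a decimated grid (50 ms) for speed
  d <- max(1L, round(rec$rate * 0.05))
  gi <- seq(1L, n, by = d)
  env_d <- env[gi]
  kk <- max(3L, round(stat_window / 0.05))
  if (kk %% 2L == 0L) kk <- kk + 1L
  kk <- min(kk, if (length(gi) %% 2L == 0L) length(gi) - 1L else length(gi))
  if (kk < 3L) return(rec)
  med_d <- stats::runmed(env_d, kk, endrule = "median")
  mad_d <- stats::runmed(abs(env_d - med_d), kk, endrule = "median")
  med <- stats::approx(gi, med_d, xout = seq_len(n), rule = 2)$y
  mad <- stats::approx(gi, mad_d, xout = seq_len(n), rule = 2)$y

  flag <- env > med + k * pmax(mad, mad_floor * med)
  if (!any(flag)) return(rec)

  # dilate flagged runs by half a window
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  flag2 <- logical(n)
  for (j in which(r$values)) {
    flag2[max(1L, starts[j] - h):min(n, ends[j] + h)] <- TRUE
  }
  good <- which(!flag2)
  if (length(good) < 2L) stop("spike detector flagged the entire recording")
  y <- x
  y[flag2] <- stats::approx(good, x[good], xout = which(flag2), rule = 2)$y
  audio_recording(y, rec$rate, rec$t0)
}

#' Standard preprocessing chain
#'
#' Band-pass (zero-phase), resample, ambient-noise suppression, spike
#' removal — in that order.
#'
#' @param rec Raw [audio_recording()].
#' @param low,high Band edges, Hz.
#' @param target_rate Rate after resampling, Hz.
#' @param denoise,despike Logical stage toggles.
#' @param denoise_cfg A [denoise_config()].
#' @param spike_window,spike_k Spike-removal parameters.
#' @return The cleaned `audio_recording`.
#' @export
preprocess_audio <- function(rec, low = 100, high = 3000, target_rate = 6000,
                             denoise = TRUE, despike = TRUE,
                             denoise_cfg = denoise_config(),
                             spike_window = 0.1, spike_k = 5) {
  out <- bandpass_filter(rec, low = low, high = high)
  out <- resample_audio(out, target_rate = target_rate)
  if (denoise) out <- denoise_ambient(out, denoise_cfg)
  if (despike) out <- remove_spikes(out, window = spike_window, k = spike_k)
  out
}
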