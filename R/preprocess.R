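#' Downsample a recording
#'
#' Anti-aliased polyphase resampling of every channel to `target_fs`
#' (rational-ratio resampling via the `signal` package). Upsampling is not
#' supported.
#'
#' @param rec An [ieeg_recording()].
#' @param target_fs Target sampling rate in Hz (default 2560).
#' @return An [ieeg_recording()] at `target_fs`; sample count scales by
#'   `target_fs / fs` (rounded).
#' @export
downsample <- function(rec, target_fs = 2560) {
  stopifnot(inherits(rec, "ieeg_recording"))
  if (target_fs > rec$fs_hz) {
    abort("`target_fs` exceeds the recording sampling rate (no upsampling).",
          class = "hfo_config_error")
  }
  if (target_fs == rec$fs_hz) return(rec)
  frac <- ratio_pq(target_fs / rec$fs_hz)
  n_out <- round(n_samples(rec) * target_fs / rec$fs_hz)
  y <- matrix(0, n_channels(rec), n_out)
  for (ch in seq_len(n_channels(rec))) {
    z <- signal::resample(rec$samples[ch, ], frac$p, frac$q)
    if (length(z) >= n_out) z <- z[seq_len(n_out)] else z <- c(z, rep(0, n_out - length(z)))
    y[ch, ] <- z
  }
  ieeg_recording(y, fs_hz = target_fs, channel_labels = rec$channel_labels)
}

# small continued-fraction rational approximation of a ratio in (0, 1]
ratio_pq <- function(r, max_den = 10000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err == 0) break
  }
  list(p = best[1], q = best[2])
}

#' Cut a recording into consecutive analysis segments
#'
#' Non-overlapping windows of `window_ms` per channel; a trailing partial
#' window is discarded. Returns an empty table when the recording is shorter
#' than one window.
#'
#' @param rec An [ieeg_recording()].
#' @param window_ms Window length in milliseconds (default 150, the analysis
#'   segment length used throughout the detector).
#' @return A tibble with columns `channel`, `start_sample`, `fs_hz` and a
#'   list-column `samples` (each of length `round(window_ms/1000 * fs)`).
#' @export
segment_recording <- function(rec, window_ms = 150) {
  stopifnot(inherits(rec, "ieeg_recording"))
  w <- round(window_ms / 1000 * rec$fs_hz)
  n <- n_samples(rec)
  k <- n %/% w
  if (k == 0) {
    return(tibble(channel = integer(), start_sample = integer(),
                  fs_hz = numeric(), samples = list()))
  }
  rows <- vector("list", n_channels(rec) * k)
  idx <- 1L
  for (ch in seq_len(n_channels(rec))) {
    for (j in seq_len(k)) {
      s0 <- (j - 1L) * w + 1L
      rows[[idx]] <- tibble(channel = ch, start_sample = s0, fs_hz = rec$fs_hz,
                            samples = list(rec$samples[ch, s0:(s0 + w - 1L)]))
      idx <- idx + 1L
    }
  }
  dplyr::bind_rows(rows)
}

# zero-phase IIR filtering with reflected-edge padding (three filter lengths
# on each side), run forward then backward so the net phase response is zero
zp_filter <- function(b, a, x) {
  n <- length(x)
  if (n == 0) return(x)
  nf <- max(length(a), length(b))
  pad <- min(9L * (nf - 1L), n - 1L)
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[(pad + 1L):2L]
    tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xe <- c(head_ref, x, tail_ref)
  } else xe <- x
  y <- signal::filter(b, a, xe)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Remove mains interference with a 50 Hz multi-notch filter
#'
#' Cascaded second-order IIR notches (Q = 30) applied zero-phase. By default
#' only the 50 Hz fundamental is notched: harmonics of 50 Hz that fall inside
#' the 80-500 Hz detection band would carve narrow slices out of genuine HFO
#' spectra, so scrubbing them is opt-in -- pass
#' `freqs = seq(50, 500, by = 50)` to attenuate every harmonic up to 500 Hz.
#' The passband away from the notches is flat to within 1 dB.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz (> 100).
#' @param q Notch quality factor.
#' @param freqs Notch centre frequencies in Hz.
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, q = 30, freqs = 50) {
  if (fs <= 100) abort("`fs` must exceed 100 Hz.", class = "hfo_config_error")
  freqs <- freqs[freqs < fs / 2 * 0.98]
  y <- x
  for (f0 in freqs) {
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * q)
    b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
    a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
    y <- zp_filter(b, a, y)
  }
  y
}

#' Band-pass filter for the HFO detection band
#'
#' 4th-order Butterworth band-pass (default 80-500 Hz) applied
#' forward-backward (zero net phase, effective order doubled).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz; `fs/2` must exceed the upper band edge.
#' @param band Length-2 numeric, pass band in Hz.
#' @param order Butterworth order of the one-way filter.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, band = c(80, 500), order = 4) {
  if (fs / 2 <= band[2]) {
    abort("Nyquist frequency must exceed the upper band edge.",
          class = "hfo_config_error")
  }
  bt <- signal::butter(order, band / (fs / 2), type = "pass")
  zp_filter(bt$b, bt$a, x)
}

#' Apply the full pre-processing chain to a recording
#'
#' Notch (50 Hz + harmonics) followed by the 80-500 Hz band-pass, either on
#' each continuous channel (`mode = "continuous"`, the pipeline default --
#' candidate detection scans a continuous energy trace) or independently on
#' each 150 ms segment which is then re-concatenated
#' (`mode = "per_segment"`).
#'
#' @param rec An [ieeg_recording()].
#' @param mode `"continuous"` or `"per_segment"`.
#' @param window_ms Segment length for per-segment mode.
#' @param notch_freqs Notch centre frequencies passed to [notch_filter()].
#' @return An [ieeg_recording()] containing the filtered samples.
#' @export
preprocess_recording <- function(rec, mode = c("continuous", "per_segment"),
                                 window_ms = 150, notch_freqs = 50) {
  mode <- match.arg(mode)
  fs <- rec$fs_hz
  y <- rec$samples
  if (mode == "continuous") {
    for (ch in seq_len(n_channels(rec))) {
      y[ch, ] <- bandpass_filter(notch_filter(y[ch, ], fs,
                                              freqs = notch_freqs), fs)
    }
  } else {
    w <- round(window_ms / 1000 * fs)
    n <- n_samples(rec)
    k <- n %/% w
    for (ch in seq_len(n_channels(rec))) {
      for (j in seq_len(k)) {
        s0 <- (j - 1L) * w + 1L
        seg <- y[ch, s0:(s0 + w - 1L)]
        y[ch, s0:(s0 + w - 1L)] <-
          bandpass_filter(notch_filter(seg, fs, freqs = notch_freqs), fs)
      }
      if (k * w < n) {    # trailing partial window, filtered as-is
        seg <- y[ch, (k * w + 1L):n]
        if (length(seg) > 8) {
          y[ch, (k * w + 1L):n] <-
            bandpass_filter(notch_filter(seg, fs, freqs = notch_freqs), fs)
        }
      }
    }
  }
  ieeg_recording(y, fs, rec$channel_labels)
}
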