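#' Continuous wavelet transform with generalized Morse wavelets
#'
#' Magnitude scalogram of the analytic generalized Morse wavelet (default
#' gamma = 3, beta = 20, i.e. time-bandwidth product 60) over a geometric
#' frequency grid covering at least 60-600 Hz with `voices` voices per
#' octave. Computed in the frequency domain; the wavelet is band-pass
#' normalized (peak value 2) so a unit-amplitude sinusoid yields magnitude
#' close to 1 at its frequency.
#'
#' @param window Numeric signal vector (>= 64 samples).
#' @param fs Sampling rate in Hz; `fs/2` must exceed the top of `freq_range`.
#' @param gamma,beta Morse shape parameters.
#' @param voices Voices per octave of the scale grid.
#' @param freq_range Length-2 vector, frequency span in Hz.
#' @return An object of class `tfm`: list with `magnitude`
#'   (frequency x time), `freqs_hz`, `times_s`.
#' @examples
#' x <- sin(2 * pi * 150 * seq(0, 0.15, by = 1 / 2560))
#' m <- cwt_morse(x, 2560)
#' m$freqs_hz[which.max(m$magnitude[, ncol(m$magnitude) %/% 2])]
#' @export
cwt_morse <- function(window, fs, gamma = 3, beta = 20, voices = 16,
                      freq_range = c(60, 600)) {
  if (length(window) < 64) abort("`window` must hold at least 64 samples.",
                                 class = "hfo_config_error")
  if (fs / 2 <= freq_range[2]) {
    abort("Sampling rate too low for the requested frequency range.",
          class = "hfo_config_error")
  }
  n <- length(window)
  k_max <- ceiling(voices * log2(freq_range[2] / freq_range[1]))
  freqs <- freq_range[1] * 2^((0:k_max) / voices)
  omega_p <- (beta / gamma)^(1 / gamma)       # wavelet peak radian frequency
  X <- fft(window)
  w_grid <- 2 * pi * (0:(n - 1)) / n          # DFT radian frequencies
  pos <- w_grid <= pi                          # analytic: positive half only
  mag <- matrix(0, length(freqs), n)
  ln_peak <- beta * log(omega_p) - omega_p^gamma
  for (j in seq_along(freqs)) {
    s <- omega_p * fs / (2 * pi * freqs[j])   # scale for this centre freq
    wv <- numeric(n)
    sw <- s * w_grid[pos]
    ok <- sw > 0
    # log-domain evaluation avoids overflow of omega^beta for large beta
    wv[pos][ok] <- 2 * exp(beta * log(sw[ok]) - sw[ok]^gamma - ln_peak)
    mag[j, ] <- Mod(fft(X * wv, inverse = TRUE)) / n
  }
  structure(list(magnitude = mag, freqs_hz = freqs,
                 times_s = (seq_len(n) - 1) / fs),
            class = "tfm")
}

#' @export
print.tfm <- function(x, ...) {
  cat(sprintf("<tfm> %d frequencies (%.0f-%.0f Hz) x %d time points\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s)))
  invisible(x)
}

# blue -> red colormap ("jet" body without its dark endpoints, so the lowest
# energy is pure blue and the highest pure red); v in [0, 1]
jet_rgb <- function(v, channel = c("r", "g", "b")) {
  channel <- match.arg(channel)
  vp <- 0.125 + 0.75 * v
  centre <- switch(channel, r = 3, g = 2, b = 1)
  pmin(pmax(1.5 - abs(4 * vp - centre), 0), 1)
}

# min-max normalization with the degenerate conventions the renderer needs:
# an all-zero map stays 0 (colormap low end), any other constant map maps to
# 0.5 (mid colormap)
minmax_norm <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo < .Machine$double.eps) {
    if (abs(hi) < .Machine$double.eps) return(m * 0)
    return(m * 0 + 0.5)
  }
  (m - lo) / (hi - lo)
}

# endpoint-aligned bilinear interpolation matrix mapping length n -> m
interp_matrix <- function(n, m) {
  A <- matrix(0, m, n)
  if (n == 1) { A[, 1] <- 1; return(A) }
  s <- 1 + (seq_len(m) - 1) * (n - 1) / (m - 1)
  lo <- pmin(floor(s), n - 1)
  wt <- s - lo
  for (i in seq_len(m)) {
    A[i, lo[i]] <- 1 - wt[i]
    A[i, lo[i] + 1] <- A[i, lo[i] + 1] + wt[i]
  }
  A
}

# area-averaging (box) resampling matrix mapping length n -> m (m <= n or not)
area_matrix <- function(n, m) {
  A <- matrix(0, m, n)
  edges_t <- seq(0, n, length.out = m + 1)
  for (i in seq_len(m)) {
    a <- edges_t[i]; b <- edges_t[i + 1]
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:j1) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) A[i, j] <- ov
    }
    A[i, ] <- A[i, ] / (b - a)
  }
  A
}

# memoised geometry matrices (keyed by dimensions)
.tfm_cache <- new.env(parent = emptyenv())
cached_matrix <- function(kind, n, m) {
  key <- paste(kind, n, m, sep = "_")
  if (is.null(.tfm_cache[[key]])) {
    .tfm_cache[[key]] <- switch(kind, interp = interp_matrix(n, m),
                                area = area_matrix(n, m))
  }
  .tfm_cache[[key]]
}

#' Render a time-frequency map as an RGB raster
#'
#' Per-map min-max normalized magnitude passed through a blue-to-red
#' colormap (dominant components in red) and rasterized to exactly
#' 875 x 656 x 3 by bilinear interpolation. The first raster dimension is
#' time, the second frequency (ascending), values in `[0, 1]`.
#'
#' @param map A `tfm` from [cwt_morse()].
#' @param raster_dim Output raster size (time, frequency).
#' @return A numeric array of dimension `c(875, 656, 3)`.
#' @export
render_tfm <- function(map, raster_dim = c(875, 656)) {
  stopifnot(inherits(map, "tfm"))
  P <- minmax_norm(map$magnitude)            # freq x time
  A <- cached_matrix("interp", ncol(P), raster_dim[1])   # time axis
  B <- cached_matrix("interp", nrow(P), raster_dim[2])   # freq axis
  U <- A %*% t(P) %*% t(B)                   # time x freq
  out <- array(0, c(raster_dim, 3L))
  out[, , 1] <- jet_rgb(U, "r")
  out[, , 2] <- jet_rgb(U, "g")
  out[, , 3] <- jet_rgb(U, "b")
  out
}

#' Extract the red-channel surrogate image (R-TFM)
#'
#' Takes the red channel of a rendered map, rescales to `[0, 1]` (0-255
#' integer rasters are divided by 255) and area-resizes it to exactly
#' 64 x 64. The red channel of the blue-to-red colormap behaves as a soft
#' threshold on normalized energy, so high-energy "islands" survive and the
#' blue background is suppressed.
#'
#' @param rgb A 3-channel raster array (time x frequency x 3).
#' @param size Output side length (64).
#' @return A `size` x `size` matrix (class `rtfm`) with values in `[0, 1]`;
#'   rows index time, columns frequency.
#' @export
extract_rtfm <- function(rgb, size = 64) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3) {
    abort("`rgb` must be a 3-channel raster.", class = "hfo_config_error")
  }
  red <- rgb[, , 1]
  if (max(red) > 1) red <- red / 255
  A <- cached_matrix("area", d[1], size)
  B <- cached_matrix("area", d[2], size)
  out <- A %*% red %*% t(B)
  out <- pmin(pmax(out, 0), 1)
  class(out) <- c("rtfm", class(out))
  out
}

#' Compute the R-TFM of a candidate window in one step
#'
#' Equivalent to `cwt_morse() |> render_tfm() |> extract_rtfm()` but skips
#' the green and blue channels of the intermediate raster; identical output
#' to the full path (exercised in the test suite).
#'
#' @inheritParams cwt_morse
#' @param raster_dim Intermediate raster size.
#' @param size Output side length.
#' @return An `rtfm` matrix.
#' @export
window_rtfm <- function(window, fs, gamma = 3, beta = 20, voices = 16,
                        freq_range = c(60, 600), raster_dim = c(875, 656),
                        size = 64) {
  map <- cwt_morse(window, fs, gamma, beta, voices, freq_range)
  P <- minmax_norm(map$magnitude)
  A <- cached_matrix("interp", ncol(P), raster_dim[1])
  B <- cached_matrix("interp", nrow(P), raster_dim[2])
  red <- jet_rgb(A %*% t(P) %*% t(B), "r")
  A2 <- cached_matrix("area", raster_dim[1], size)
  B2 <- cached_matrix("area", raster_dim[2], size)
  out <- pmin(pmax(A2 %*% red %*% t(B2), 0), 1)
  class(out) <- c("rtfm", class(out))
  out
}
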