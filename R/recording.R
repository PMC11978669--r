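#' iEEG recording container
#'
#' A minimal in-memory representation of a multichannel intracranial EEG
#' recording: a channels-by-samples numeric matrix plus its sampling rate and
#' channel labels. All pipeline stages accept and return this class.
#'
#' @param samples Numeric matrix, channels x time, in microvolts. A vector is
#'   treated as a single channel.
#' @param fs_hz Sampling rate in Hz (positive scalar).
#' @param channel_labels Optional character vector of channel names; defaults
#'   to `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `ieeg_recording` with fields `samples`, `fs_hz`
#'   and `channel_labels`.
#' @examples
#' rec <- ieeg_recording(matrix(rnorm(512), nrow = 1), fs_hz = 256)
#' rec
#' @export
ieeg_recording <- function(samples, fs_hz, channel_labels = NULL) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1)
  }
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    abort("`fs_hz` must be a positive scalar.", class = "hfo_config_error")
  }
  n_ch <- nrow(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n_ch))
  stopifnot(length(channel_labels) == n_ch)
  structure(
    list(samples = samples, fs_hz = fs_hz,
         channel_labels = as.character(channel_labels)),
    class = "ieeg_recording"
  )
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf(
    "<ieeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
    nrow(x$samples), ncol(x$samples), x$fs_hz, ncol(x$samples) / x$fs_hz
  ))
  invisible(x)
}

#' @export
dim.ieeg_recording <- function(x) dim(x$samples)

n_samples <- function(rec) ncol(rec$samples)
n_channels <- function(rec) nrow(rec$samples)
rec_duration_s <- function(rec) ncol(rec$samples) / rec$fs_hz
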