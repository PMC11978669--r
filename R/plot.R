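#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time-frequency map
#'
#' Magnitude scalogram on a logarithmic frequency axis; the colour fill uses
#' the same blue-to-red mapping as the rendered raster.
#'
#' @param object A `tfm` from [cwt_morse()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tfm <- function(object, ...) {
  df <- tibble(
    time_s = rep(object$times_s, each = length(object$freqs_hz)),
    freq_hz = rep(object$freqs_hz, times = length(object$times_s)),
    magnitude = as.vector(object$magnitude)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradientn(colours = c("#00007F", "blue", "cyan",
                                              "yellow", "red")) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "|CWT|")
}

#' Plot an R-TFM surrogate image
#'
#' @param object An `rtfm` (64x64 matrix in `[0, 1]`).
#' @param ... Unused.
#' @return A ggplot (rows = time, columns = frequency bins, low at left).
#' @export
autoplot.rtfm <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(
    time_bin = rep(seq_len(nrow(m)), times = ncol(m)),
    freq_bin = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_bin, .data$freq_bin,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "time bin", y = "frequency bin", fill = "red channel")
}

#' Plot the training-loss history of a CVAE fit
#'
#' @param object A `cvae_fit`.
#' @param ... Unused.
#' @return A ggplot of negative-ELBO loss per epoch.
#' @export
autoplot.cvae_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_history,
                  ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "negative ELBO")
}

#' Plot detected events along the recording
#'
#' One point per candidate at its centre time, coloured by assigned class;
#' the y position is the spectral centroid.
#'
#' @param object A `detection_report`.
#' @param fs_hz Sampling rate used to convert centre samples to seconds
#'   (taken from the report's candidates when available).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.detection_report <- function(object, fs_hz = NULL, ...) {
  ev <- object$events
  if (nrow(ev) == 0) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "no events"))
  }
  if (is.null(fs_hz)) fs_hz <- object$candidates$fs_hz[1]
  ev$time_s <- ev$center_sample / fs_hz
  ggplot2::ggplot(ev, ggplot2::aes(.data$time_s, .data$sc_hz,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "spectral centroid (Hz)",
                  colour = "class")
}
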