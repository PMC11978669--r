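#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted CVAE
#'
#' @param x A `cvae_fit`.
#' @param ... Unused.
#' @return The per-epoch loss history as a tibble (`epoch`, `loss`).
#' @export
tidy.cvae_fit <- function(x, ...) x$loss_history

#' One-row summary of a fitted CVAE
#'
#' @param x A `cvae_fit`.
#' @param ... Unused.
#' @return A tibble with the latent size, epochs, parameter count and the
#'   first/final training loss.
#' @export
glance.cvae_fit <- function(x, ...) {
  tibble(
    latent_dim = x$config$latent_dim,
    epochs = x$config$epochs,
    n_parameters = sum(vapply(x$model$params, length, 0L)),
    first_loss = x$loss_history$loss[1],
    final_loss = x$loss_history$loss[nrow(x$loss_history)]
  )
}

#' Tidy a clustering result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return One row per cluster: size, assigned class and mean spectral
#'   centroid (when classes have been assigned).
#' @export
tidy.cluster_result <- function(x, ...) {
  sizes <- tabulate(x$labels, x$K)
  out <- tibble(cluster = seq_len(x$K), size = sizes)
  if (!is.null(x$class_map)) {
    out$class <- x$class_map
    out$mean_sc_hz <- vapply(seq_len(x$K), function(k) {
      if (sizes[k] == 0) NA_real_ else mean(x$sc_hz[x$labels == k])
    }, 0)
  }
  out
}

#' Per-event table of a detection report
#'
#' @param x A `detection_report`.
#' @param ... Unused.
#' @return The events tibble (one row per candidate).
#' @export
tidy.detection_report <- function(x, ...) x$events

#' One-row summary of a detection report
#'
#' @param x A `detection_report`.
#' @param ... Unused.
#' @return A tibble with candidate/HFO counts and, when ground truth was
#'   supplied, the binary metrics and STE detection recall.
#' @export
glance.detection_report <- function(x, ...) {
  out <- tibble(
    n_events = nrow(x$events),
    n_hfo = if (nrow(x$events)) sum(x$events$is_hfo) else 0L
  )
  if (!is.null(x$metrics)) {
    out <- dplyr::bind_cols(out, as_tibble(x$metrics))
    out$detection_sensitivity <- x$detection_sensitivity
  }
  out
}
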