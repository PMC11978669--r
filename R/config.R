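#' Read pipeline and generator configuration from YAML
#'
#' Maps a YAML file with optional top-level blocks `synth`, `ste`, `tfm`,
#' `cvae` and `cluster` onto [synth_config()] / [pipeline_config()]
#' arguments; fields not present keep their defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `synth` (a `synth_config`) and `pipeline`
#'   (a `pipeline_config`).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sy <- y$synth %||% list()
  syn <- do.call(synth_config, sy[names(sy) %in% names(formals(synth_config))])
  cv <- y$cvae %||% list()
  cvae <- do.call(cvae_config, cv[names(cv) %in% names(formals(cvae_config))])
  pl <- list(cvae = cvae)
  if (!is.null(y$ste$k)) pl$ste_k <- y$ste$k
  if (!is.null(y$ste$frame_ms)) pl$ste_frame_ms <- y$ste$frame_ms
  if (!is.null(y$ste$min_consecutive)) pl$min_consecutive <- y$ste$min_consecutive
  if (!is.null(y$cluster$method)) pl$cluster_method <- y$cluster$method
  if (!is.null(y$cluster$K)) pl$K <- y$cluster$K
  if (!is.null(y$cluster$seed)) pl$seed <- y$cluster$seed
  if (!is.null(y$cluster$sc_on)) pl$sc_on <- y$cluster$sc_on
  if (!is.null(y$use_cvae)) pl$use_cvae <- y$use_cvae
  if (!is.null(y$target_fs)) pl$target_fs <- y$target_fs
  list(synth = syn, pipeline = do.call(pipeline_config, pl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
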