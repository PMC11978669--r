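#' Confusion-matrix metrics for binary HFO detection
#'
#' Positive = real HFO (ripple or fast ripple). Accuracy, sensitivity and
#' specificity are reported as percentages; a metric whose denominator is
#' zero is `NA`, not 0.
#'
#' @param pred Logical vector of predicted HFO flags.
#' @param truth Logical vector of true HFO flags (same length).
#' @return A one-row tibble of class `confusion_metrics` with columns `tp`,
#'   `tn`, `fp`, `fn`, `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` must have equal length.",
          class = "hfo_config_error")
  }
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = pct(tp + tn, tp + tn + fp + fn),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp)
  )
  class(out) <- c("confusion_metrics", class(out))
  out
}

#' Stratified five-fold cross-validation
#'
#' Splits the samples into `folds` stratified folds under `seed`, trains
#' `model` on the complement of each fold, evaluates on the held-out fold
#' and averages the metrics over folds.
#'
#' @param X Feature matrix, samples x features.
#' @param y Logical (binary) labels; positives are HFOs.
#' @param model Model spec: one of `"knn"`, `"svm_linear"`, `"svm_poly"`,
#'   `"svm_rbf"`, or a function `f(X_train, y_train, X_test)` returning
#'   predicted logical labels.
#' @param seed Integer seed for the fold assignment.
#' @param folds Number of folds.
#' @param fold_id Optional explicit fold assignment (integer vector in
#'   `1..folds`), overriding the seeded stratified split.
#' @return A `confusion_metrics` row of fold-averaged metrics, with the
#'   per-fold table in `attr(, "folds")`.
#' @export
five_fold_cv <- function(X, y, model, seed = 1, folds = 5, fold_id = NULL) {
  X <- as.matrix(X); y <- as.logical(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (is.null(fold_id)) {
    fold_id <- integer(n)
    with_seed(seed, {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))
      }
    })
  }
  for (f in seq_len(folds)) {
    if (length(unique(y[fold_id == f])) < 2 ||
        length(unique(y[fold_id != f])) < 2) {
      abort("Stratification failure: a class is absent from a fold.",
            class = "hfo_stratification_error")
    }
  }
  fit_fun <- if (is.function(model)) model else baseline_fun(model)
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f; te <- !tr
    pred <- fit_fun(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
    cm <- confusion(pred, y[te])
    cm$fold <- f
    cm
  })
  fold_tbl <- dplyr::bind_rows(per_fold)
  out <- tibble(
    tp = sum(fold_tbl$tp), tn = sum(fold_tbl$tn),
    fp = sum(fold_tbl$fp), fn = sum(fold_tbl$fn),
    accuracy = mean(fold_tbl$accuracy),
    sensitivity = mean(fold_tbl$sensitivity),
    specificity = mean(fold_tbl$specificity)
  )
  class(out) <- c("confusion_metrics", class(out))
  attr(out, "folds") <- fold_tbl
  out
}

# the supervised reference models; positives coded 1 (R and FR), negatives 0
baseline_fun <- function(model) {
  switch(model,
    knn = function(Xtr, ytr, Xte) {
      as.logical(as.integer(as.character(
        class::knn(Xtr, Xte, factor(as.integer(ytr)), k = 5)
      )))
    },
    svm_linear = svm_fun("linear"),
    svm_poly = svm_fun("polynomial"),
    svm_rbf = svm_fun("radial"),
    abort(sprintf("Unknown baseline model '%s'.", model))
  )
}

svm_fun <- function(kernel) {
  function(Xtr, ytr, Xte) {
    if (length(unique(ytr)) < 2) {
      abort("Degenerate single-class training data.",
            class = "hfo_config_error")
    }
    fit <- e1071::svm(Xtr, factor(as.integer(ytr)), kernel = kernel,
                      scale = FALSE)
    as.logical(as.integer(as.character(predict(fit, Xte))))
  }
}

#' Supervised baseline classifiers
#'
#' KNN (k = 5) and SVM (linear, polynomial or Gaussian kernel, default
#' regularisation), evaluated by stratified [five_fold_cv()] on binary HFO
#' labels.
#'
#' @param X Feature matrix (vectorized R-TFMs).
#' @param y Logical labels; `TRUE` = real HFO (ripple or fast ripple).
#' @param model `"knn"`, `"svm_linear"`, `"svm_poly"` or `"svm_rbf"`.
#' @param seed Fold seed.
#' @return A `confusion_metrics` row.
#' @export
supervised_baseline <- function(X, y, model = c("knn", "svm_linear",
                                                "svm_poly", "svm_rbf"),
                                seed = 1) {
  model <- match.arg(model)
  if (length(unique(as.logical(y))) < 2) {
    abort("Degenerate single-class data.", class = "hfo_config_error")
  }
  five_fold_cv(X, y, model, seed = seed)
}

# ---------------------------------------------------------------------------

#' Match detected candidates against ground-truth annotations
#'
#' A candidate matches the nearest annotation on the same channel within
#' `tol_ms` of its centre; unmatched candidates get `true_kind = NA`
#' (background detections, negatives in the binary evaluation).
#'
#' @param candidates Candidate table ([detect_candidates_recording()]).
#' @param annotations Annotation table ([make_benchmark()]).
#' @param tol_ms Matching tolerance in milliseconds.
#' @return The candidate table with `true_kind` and `truth_hfo` columns.
#' @export
match_candidates <- function(candidates, annotations, tol_ms = 75) {
  if (nrow(candidates) == 0) {
    candidates$true_kind <- character(0)
    candidates$truth_hfo <- logical(0)
    return(candidates)
  }
  kind <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    tol <- tol_ms / 1000 * candidates$fs_hz[i]
    ann <- annotations[annotations$channel == candidates$channel[i], ]
    if (nrow(ann) == 0) next
    d <- abs(ann$center_sample - candidates$center_sample[i])
    j <- which.min(d)
    if (d[j] <= tol) kind[i] <- ann$kind[j]
  }
  candidates$true_kind <- kind
  candidates$truth_hfo <- !is.na(kind) & kind %in% c("ripple", "fast_ripple")
  candidates
}

#' Fraction of annotated events that produced a candidate
#'
#' @param candidates Candidate table.
#' @param annotations Annotation table.
#' @param kinds Annotation kinds to score (default: the oscillatory ones,
#'   for the sensitivity-first detection contract).
#' @param tol_ms Matching tolerance in milliseconds.
#' @return Scalar in `[0, 1]`.
#' @export
detection_sensitivity <- function(candidates, annotations,
                                  kinds = c("ripple", "fast_ripple"),
                                  tol_ms = 75) {
  ann <- annotations[annotations$kind %in% kinds, ]
  if (nrow(ann) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(ann)), function(i) {
    cc <- candidates[candidates$channel == ann$channel[i], ]
    if (nrow(cc) == 0) return(FALSE)
    tol <- tol_ms / 1000 * cc$fs_hz[1]
    any(abs(cc$center_sample - ann$center_sample[i]) <= tol)
  }, TRUE)
  mean(hit)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end detector with its default.
#'
#' @param target_fs Working sampling rate (Hz); recordings above it are
#'   downsampled.
#' @param ste_k STE threshold weight.
#' @param ste_frame_ms STE frame length (ms).
#' @param min_consecutive Supra-threshold frames required.
#' @param cluster_method `"fcm"`, `"kmeans"`, `"gmm"` or `"meanshift"`.
#' @param K Cluster count.
#' @param sc_on Window used for spectral centroids (`"raw"`/`"filtered"`).
#' @param use_cvae Reconstruct R-TFMs through the CVAE before clustering?
#' @param cvae A [cvae_config()].
#' @param seed Seed for clustering (and fold assignment downstream).
#' @param notch_freqs Notch centres (Hz) for pre-processing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_fs = 2560, ste_k = 5, ste_frame_ms = 10,
                            min_consecutive = 3,
                            cluster_method = c("fcm", "kmeans", "gmm",
                                               "meanshift"),
                            K = 4, sc_on = c("raw", "filtered"),
                            use_cvae = TRUE, cvae = cvae_config(),
                            seed = 1, notch_freqs = 50) {
  structure(list(target_fs = target_fs, ste_k = ste_k,
                 ste_frame_ms = ste_frame_ms,
                 min_consecutive = min_consecutive,
                 cluster_method = match.arg(cluster_method), K = K,
                 sc_on = match.arg(sc_on), use_cvae = use_cvae, cvae = cvae,
                 seed = seed, notch_freqs = notch_freqs),
            class = "pipeline_config")
}

cluster_by_method <- function(method, X, K, seed) {
  switch(method,
    fcm = fcm_cluster(X, K, seed = seed),
    kmeans = kmeans_cluster(X, K, seed = seed),
    gmm = gmm_cluster(X, K, seed = seed),
    meanshift = meanshift_cluster(X, reduce_to = K, seed = seed),
    abort(sprintf("Unknown cluster method '%s'.", method))
  )
}

#' Run the full unsupervised HFO detection pipeline
#'
#' Pre-processing (downsample, notch, band-pass), STE candidate screening,
#' Morse-CWT R-TFM imaging, CVAE training and reconstruction, clustering,
#' and spectral-centroid class assignment; when ground-truth annotations are
#' supplied, the binary confusion metrics are computed over the candidates.
#'
#' @param recording An [ieeg_recording()].
#' @param config A [pipeline_config()].
#' @param annotations Optional ground-truth table ([make_benchmark()]).
#' @param verbose Report stage progress?
#' @return An object of class `detection_report`: list with `events` (one
#'   row per candidate: channel, centre, cluster, class, SC, HFO flag,
#'   matched truth), `metrics` (a `confusion_metrics` row or NULL),
#'   `detection_sensitivity`, `cvae_fit`, `cluster_result`, `config`.
#' @export
run_pipeline <- function(recording, config = pipeline_config(),
                         annotations = NULL, verbose = FALSE) {
  stopifnot(inherits(recording, "ieeg_recording"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (recording$fs_hz > config$target_fs) {
    say("downsampling %g -> %g Hz", recording$fs_hz, config$target_fs)
    recording <- downsample(recording, config$target_fs)
  }
  say("filtering %d channel(s)", n_channels(recording))
  filtered <- preprocess_recording(recording, notch_freqs = config$notch_freqs)
  say("detecting candidates (k = %g)", config$ste_k)
  cands <- detect_candidates_recording(filtered, recording, k = config$ste_k,
                                       frame_ms = config$ste_frame_ms,
                                       min_consecutive = config$min_consecutive)
  if (!is.null(annotations)) cands <- match_candidates(cands, annotations)
  if (nrow(cands) == 0) {
    say("no candidates above threshold")
    return(structure(list(events = tibble(), metrics = NULL,
                          detection_sensitivity = if (is.null(annotations))
                            NA_real_ else
                              detection_sensitivity(cands, annotations),
                          cvae_fit = NULL, cluster_result = NULL,
                          config = config),
                     class = "detection_report"))
  }
  say("imaging %d candidates", nrow(cands))
  rtfms <- lapply(cands$raw_window, window_rtfm, fs = cands$fs_hz[1])
  imgs <- rtfms
  fit <- NULL
  if (config$use_cvae) {
    say("training CVAE (l = %d, %d epochs)", config$cvae$latent_dim,
        config$cvae$epochs)
    fit <- train_cvae(rtfms, config$cvae)
    imgs <- cvae_reconstruct(fit, rtfms)
  }
  say("clustering (%s, K = %d)", config$cluster_method, config$K)
  X <- images_to_features(imgs)
  cl <- cluster_by_method(config$cluster_method, X, config$K, config$seed)
  cl <- assign_classes(cl, cands, sc_on = config$sc_on)
  events <- tibble(
    channel = cands$channel,
    center_sample = cands$center_sample,
    peak_ste = cands$peak_ste,
    cluster_id = cl$labels,
    class = cl$class,
    sc_hz = cl$sc_hz,
    is_hfo = cl$is_hfo
  )
  metrics <- NULL; det_sens <- NA_real_
  if (!is.null(annotations)) {
    events$true_kind <- cands$true_kind
    events$truth_hfo <- cands$truth_hfo
    metrics <- confusion(events$is_hfo, events$truth_hfo)
    det_sens <- detection_sensitivity(cands, annotations)
  }
  structure(list(events = events, metrics = metrics,
                 detection_sensitivity = det_sens, cvae_fit = fit,
                 cluster_result = cl, config = config,
                 rtfms = rtfms, reconstructions = if (config$use_cvae) imgs,
                 candidates = cands),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> %d candidate event(s)\n", nrow(x$events)))
  if (nrow(x$events) > 0) print(table(class = x$events$class))
  if (!is.null(x$metrics)) {
    cat(sprintf(
      "accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  (STE recall %.1f%%)\n",
      x$metrics$accuracy, x$metrics$sensitivity, x$metrics$specificity,
      100 * x$detection_sensitivity))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------

# 64x64x3 colour representation of the full TFM (for the representation
# ablation): every colormap channel of the rendered map, area-resized
window_tfm_features <- function(window, fs, raster_dim = c(875, 656),
                                size = 64) {
  map <- cwt_morse(window, fs)
  P <- minmax_norm(map$magnitude)
  A <- cached_matrix("interp", ncol(P), raster_dim[1])
  B <- cached_matrix("interp", nrow(P), raster_dim[2])
  U <- A %*% t(P) %*% t(B)
  A2 <- cached_matrix("area", raster_dim[1], size)
  B2 <- cached_matrix("area", raster_dim[2], size)
  c(A2 %*% jet_rgb(U, "r") %*% t(B2),
    A2 %*% jet_rgb(U, "g") %*% t(B2),
    A2 %*% jet_rgb(U, "b") %*% t(B2))
}

#' Run the model-comparison experiment grid
#'
#' Reproduces the structure of the published comparison tables on a labelled
#' candidate set: supervised baselines (KNN, three SVM kernels) under
#' five-fold CV, the four unsupervised clusterers evaluated over the whole
#' dataset after spectral-centroid class assignment, each on a chosen
#' representation -- `TFM` (colour map, 64x64x3 features), `RTFM` (red
#' channel, 64x64) or `recon_RTFM` (CVAE reconstruction of the R-TFM).
#'
#' @param candidates Candidate table with matched `truth_hfo` (see
#'   [match_candidates()]).
#' @param grid Tibble with columns `representation` and `model`; the default
#'   covers the supervised table, the unsupervised table, the CVAE-
#'   reconstructed variants and the FCM representation ablation.
#' @param cvae A [cvae_config()] used for the reconstructed representation.
#' @param seed Seed for folds and clustering.
#' @param sc_on Spectral-centroid window.
#' @param verbose Report cell progress?
#' @return A tibble: one row per grid cell with the confusion metrics.
#' @export
run_experiment_grid <- function(candidates, grid = default_grid(),
                                cvae = cvae_config(), seed = 1,
                                sc_on = "raw", verbose = FALSE) {
  stopifnot(all(c("representation", "model") %in% names(grid)))
  if (!"truth_hfo" %in% names(candidates)) {
    abort("`candidates` must carry matched ground truth (truth_hfo).",
          class = "hfo_config_error")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  fs <- candidates$fs_hz[1]
  supervised <- c("knn", "svm_linear", "svm_poly", "svm_rbf")
  say("imaging %d candidates", nrow(candidates))
  rtfms <- lapply(candidates$raw_window, window_rtfm, fs = fs)
  feats <- list(RTFM = images_to_features(rtfms))
  needs <- unique(grid$representation)
  if ("TFM" %in% needs) {
    feats$TFM <- t(vapply(candidates$raw_window, window_tfm_features,
                          numeric(3 * 4096), fs = fs))
  }
  fit <- NULL
  if ("recon_RTFM" %in% needs) {
    say("training CVAE for the reconstructed representation")
    fit <- train_cvae(rtfms, cvae)
    feats$recon_RTFM <- images_to_features(cvae_reconstruct(fit, rtfms))
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rep_i <- grid$representation[i]; mod_i <- grid$model[i]
    say("cell %d/%d: %s on %s", i, nrow(grid), mod_i, rep_i)
    X <- feats[[rep_i]]
    if (is.null(X)) {
      warn(sprintf("Skipping incompatible cell %s/%s.", mod_i, rep_i))
      return(NULL)
    }
    cm <- if (mod_i %in% supervised) {
      supervised_baseline(X, candidates$truth_hfo, mod_i, seed = seed)
    } else {
      cl <- cluster_by_method(mod_i, X, 4, seed)
      cl <- assign_classes(cl, candidates, sc_on = sc_on)
      confusion(cl$is_hfo, candidates$truth_hfo)
    }
    dplyr::bind_cols(tibble(representation = rep_i, model = mod_i),
                     as_tibble(cm))
  })
  dplyr::bind_rows(rows)
}

#' @rdname run_experiment_grid
#' @export
default_grid <- function() {
  dplyr::bind_rows(
    tibble(representation = "RTFM",
           model = c("knn", "svm_linear", "svm_poly", "svm_rbf")),
    tibble(representation = "RTFM",
           model = c("meanshift", "kmeans", "gmm", "fcm")),
    tibble(representation = "recon_RTFM",
           model = c("meanshift", "kmeans", "gmm", "fcm")),
    tibble(representation = "TFM", model = "fcm")
  )
}

#' Latent-size / epoch ablation of the CVAE + FCM detector
#'
#' Trains one CVAE per (latent size, epoch budget) cell, reconstructs,
#' clusters with FCM and reports the binary metrics -- the structure of the
#' published hyper-parameter sweep.
#'
#' @param candidates Labelled candidate table.
#' @param latent_dims Integer vector of latent sizes.
#' @param epoch_grid Integer vector of training-epoch budgets.
#' @param base A [cvae_config()] supplying the remaining hyper-parameters.
#' @param seed Clustering seed.
#' @param verbose Report cell progress?
#' @return A tibble with one row per cell.
#' @export
run_latent_sweep <- function(candidates, latent_dims = c(10, 20, 30, 40, 50),
                             epoch_grid = c(100, 150, 200),
                             base = cvae_config(), seed = 1,
                             verbose = FALSE) {
  fs <- candidates$fs_hz[1]
  rtfms <- lapply(candidates$raw_window, window_rtfm, fs = fs)
  rows <- list()
  for (l in latent_dims) {
    for (ep in epoch_grid) {
      if (verbose) message(sprintf("l = %d, epochs = %d", l, ep))
      cfg <- cvae_config(latent_dim = l, epochs = ep,
                         batch_size = base$batch_size,
                         learning_rate = base$learning_rate,
                         filters = base$filters, recon_loss = base$recon_loss,
                         seed = base$seed)
      fit <- train_cvae(rtfms, cfg)
      X <- images_to_features(cvae_reconstruct(fit, rtfms))
      cl <- assign_classes(fcm_cluster(X, 4, seed = seed), candidates)
      cm <- confusion(cl$is_hfo, candidates$truth_hfo)
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(tibble(latent_dim = l, epochs = ep), as_tibble(cm))
    }
  }
  dplyr::bind_rows(rows)
}
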