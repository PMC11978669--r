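#' Column-wise vectorization of an image
#'
#' Flattens a 64x64 image column by column, so element (r, c) of the image
#' lands at position `(c - 1) * 64 + r` of the feature vector (length 4096).
#' The inverse is `matrix(v, 64, 64)`.
#'
#' @param img A 64x64 matrix (an `rtfm` or a reconstruction).
#' @return Numeric vector of length 4096.
#' @export
vectorize_rtfm <- function(img) {
  if (!is.matrix(img) || !all(dim(img) == c(64, 64))) {
    abort("`img` must be a 64x64 matrix.", class = "hfo_config_error")
  }
  as.vector(img)
}

images_to_features <- function(images) {
  t(vapply(images, function(im) as.vector(im), numeric(length(images[[1]]))))
}

new_cluster_result <- function(labels, memberships, K, method, centers = NULL) {
  structure(list(labels = as.integer(labels), memberships = memberships,
                 K = as.integer(K), method = method, centers = centers,
                 class_map = NULL),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, K = %d, n = %d\n", x$method, x$K,
              length(x$labels)))
  print(table(cluster = x$labels))
  if (!is.null(x$class_map)) {
    cat("class map:", paste(seq_along(x$class_map), x$class_map,
                            sep = " -> ", collapse = ", "), "\n")
  }
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii) under the current RNG stream
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  ci <- sample.int(n, 1)
  centers[1, ] <- X[ci, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(K - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    ci <- sample.int(n, 1, prob = p)
    centers[j + 1, ] <- X[ci, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1, ])^2))
  }
  centers
}

#' K-means clustering of feature vectors
#'
#' Lloyd's algorithm seeded by k-means++ under `seed`; memberships are
#' one-hot.
#'
#' @param X Numeric matrix, samples x features (e.g. vectorized R-TFMs).
#' @param K Number of clusters (default 4: ripple, fast ripple, spike,
#'   artifact).
#' @param seed Integer seed.
#' @param max_iter Lloyd iteration cap.
#' @return A `cluster_result`.
#' @export
kmeans_cluster <- function(X, K = 4, seed = 1, max_iter = 300) {
  X <- as.matrix(X)
  if (nrow(X) < K) abort("Fewer samples than clusters.",
                         class = "hfo_config_error")
  km <- with_seed(seed, {
    init <- kmeanspp_centers(X, K)
    kmeans(X, centers = init, iter.max = max_iter, algorithm = "Lloyd")
  })
  memb <- matrix(0, nrow(X), K)
  memb[cbind(seq_len(nrow(X)), km$cluster)] <- 1
  new_cluster_result(km$cluster, memb, K, "kmeans", km$centers)
}

#' Fuzzy c-means clustering
#'
#' Standard FCM (fuzziness `m`, default 2) via `e1071::cmeans`, seeded by
#' k-means++ centres so results are reproducible; hard labels are the
#' arg-max memberships.
#'
#' @inheritParams kmeans_cluster
#' @param m Fuzziness exponent (> 1).
#' @return A `cluster_result` with soft memberships (rows sum to 1).
#' @export
fcm_cluster <- function(X, K = 4, m = 2, seed = 1, max_iter = 300) {
  X <- as.matrix(X)
  if (nrow(X) < K) abort("Fewer samples than clusters.",
                         class = "hfo_config_error")
  fit <- with_seed(seed, {
    init <- kmeanspp_centers(X, K)
    e1071::cmeans(X, centers = init, m = m, iter.max = max_iter,
                  method = "cmeans")
  })
  new_cluster_result(fit$cluster, fit$membership, K, "fcm", fit$centers)
}

#' Gaussian-mixture clustering (diagonal covariances)
#'
#' EM for a K-component Gaussian mixture with diagonal covariances,
#' initialised from the k-means++/Lloyd partition; per-dimension variances
#' are floored at 1e-6 to survive pixel dimensions that are constant within
#' a component. Labels are the maximum-responsibility components and
#' memberships the responsibilities.
#'
#' @inheritParams kmeans_cluster
#' @param tol Relative log-likelihood convergence tolerance.
#' @param var_floor Variance regularisation floor.
#' @return A `cluster_result`.
#' @export
gmm_cluster <- function(X, K = 4, seed = 1, max_iter = 300, tol = 1e-6,
                        var_floor = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < K) abort("Fewer samples than clusters.", class = "hfo_config_error")
  hard <- kmeans_cluster(X, K, seed)$labels
  pi_k <- tabulate(hard, K) / n
  mu <- t(vapply(seq_len(K), function(k) colMeans(X[hard == k, , drop = FALSE]),
                 numeric(d)))
  va <- t(vapply(seq_len(K), function(k) {
    v <- apply(X[hard == k, , drop = FALSE], 2, function(col) mean((col - mean(col))^2))
    pmax(v, var_floor)
  }, numeric(d)))
  ll_old <- -Inf
  resp <- matrix(0, n, K)
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(K), function(k) {
      -0.5 * (colSums((t(X) - mu[k, ])^2 / va[k, ]) +
                sum(log(2 * pi * va[k, ]))) + log(max(pi_k[k], 1e-12))
    }, numeric(n))
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    resp <- exp(logp - lse)
    ll <- sum(lse)
    nk <- colSums(resp)
    pi_k <- nk / n
    for (k in seq_len(K)) {
      if (nk[k] < 1e-8) next
      mu[k, ] <- colSums(X * resp[, k]) / nk[k]
      va[k, ] <- pmax(colSums((t(t(X) - mu[k, ]))^2 * resp[, k]) / nk[k],
                      var_floor)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  new_cluster_result(max.col(resp), resp, K, "gmm", mu)
}

#' Mean-shift clustering
#'
#' Gaussian-kernel mean shift; every point iterates to its density mode and
#' modes closer than `bandwidth / 4` are merged. The data determine the
#' cluster count; when `reduce_to` is given, the nearest modes are merged
#' until at most that many clusters remain (the class-assignment stage
#' expects four).
#'
#' @inheritParams kmeans_cluster
#' @param bandwidth Kernel bandwidth; defaults to the median pairwise
#'   distance of (a subsample of) the data.
#' @param reduce_to Upper bound on the returned cluster count (NULL = keep
#'   all modes).
#' @param max_iter Mean-shift iteration cap.
#' @return A `cluster_result` (one-hot memberships).
#' @export
meanshift_cluster <- function(X, bandwidth = NULL, reduce_to = 4, seed = 1,
                              max_iter = 50) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(bandwidth)) {
    sub <- if (n > 400) with_seed(seed, sample.int(n, 400)) else seq_len(n)
    bandwidth <- median(stats::dist(X[sub, , drop = FALSE]))
  }
  if (bandwidth <= 0) abort("`bandwidth` must be positive.",
                            class = "hfo_config_error")
  M <- X
  x_sq <- rowSums(X^2)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(M^2), x_sq, "+") - 2 * M %*% t(X)
    Wk <- exp(-pmax(d2, 0) / (2 * bandwidth^2))
    Mn <- (Wk %*% X) / rowSums(Wk)
    if (max(abs(Mn - M)) < 1e-6 * bandwidth) { M <- Mn; break }
    M <- Mn
  }
  # merge converged modes
  labels <- integer(n); modes <- NULL
  for (i in seq_len(n)) {
    if (is.null(modes)) { modes <- M[i, , drop = FALSE]; labels[i] <- 1L; next }
    dd <- sqrt(rowSums(sweep(modes, 2, M[i, ])^2))
    j <- which.min(dd)
    if (dd[j] < bandwidth / 4) labels[i] <- j
    else { modes <- rbind(modes, M[i, ]); labels[i] <- nrow(modes) }
  }
  # optional reduction: repeatedly merge the two nearest modes
  if (!is.null(reduce_to)) {
    while (nrow(modes) > reduce_to) {
      dm <- as.matrix(stats::dist(modes))
      diag(dm) <- Inf
      ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
      a <- min(ij); b <- max(ij)
      wa <- sum(labels == a); wb <- sum(labels == b)
      modes[a, ] <- (wa * modes[a, ] + wb * modes[b, ]) / (wa + wb)
      labels[labels == b] <- a
      keep <- sort(unique(labels))
      labels <- match(labels, keep)
      modes <- modes[keep, , drop = FALSE]
    }
  }
  K <- nrow(modes)
  memb <- matrix(0, n, K)
  memb[cbind(seq_len(n), labels)] <- 1
  new_cluster_result(labels, memb, K, "meanshift", modes)
}

#' Spectral centroid of an event signal
#'
#' Power-weighted mean frequency of the Hamming-windowed DFT over the
#' one-sided spectrum: `SC = sum_k (k / (N T)) |M_k|^2 / sum_k |M_k|^2` for
#' `k = 0..N/2`, `T = 1/fs`. HFOs concentrate spectral mass high, spikes and
#' electrode artifacts low, which is what the class-assignment rule
#' exploits. An all-zero signal has SC 0 by convention; the SC is invariant
#' to amplitude scaling.
#'
#' @param x Numeric signal vector (a 150 ms pHFO window).
#' @param fs Sampling rate in Hz.
#' @return Spectral centroid in Hz.
#' @examples
#' spectral_centroid(sin(2 * pi * 150 * (0:383) / 2560), 2560)
#' @export
spectral_centroid <- function(x, fs) {
  n <- length(x)
  if (n == 0) abort("Empty signal.", class = "hfo_config_error")
  if (all(x == 0)) return(0)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))   # Hamming
  M2 <- Mod(fft(x * w))^2
  ks <- 0:(n %/% 2)
  p <- M2[ks + 1]
  if (sum(p) == 0) return(0)
  sum((ks * fs / n) * p) / sum(p)
}

#' Assign event classes to clusters via spectral centroids
#'
#' Computes the SC of every candidate's 150 ms window (raw by default -- the
#' pHFO proper; `sc_on = "filtered"` uses the band-passed window), averages
#' it per cluster, and maps clusters in descending mean-SC order to
#' `HFO_FR`, `HFO_R`, `spike`, `artifact`. Ties are broken by cluster size
#' (larger = more HFO-like) with a warning; empty clusters are excluded from
#' the ranking and mapped to `artifact` with a warning. The binary HFO flag
#' is `class %in% c("HFO_R", "HFO_FR")`.
#'
#' @param result A `cluster_result` with K clusters (class map is a
#'   bijection when K = 4).
#' @param candidates Candidate table from [detect_candidates_recording()]
#'   (needs `raw_window`/`filtered_window` list-columns and `fs_hz`).
#' @param sc_on `"raw"` or `"filtered"`.
#' @return The `cluster_result` augmented with `class_map` (cluster ->
#'   class), and per-event vectors `sc_hz`, `class`, `is_hfo`.
#' @export
assign_classes <- function(result, candidates, sc_on = c("raw", "filtered")) {
  stopifnot(inherits(result, "cluster_result"))
  sc_on <- match.arg(sc_on)
  if (nrow(candidates) != length(result$labels)) {
    abort("Candidate table and cluster labels disagree in length.",
          class = "hfo_config_error")
  }
  col <- if (sc_on == "raw") "raw_window" else "filtered_window"
  sc <- vapply(seq_len(nrow(candidates)), function(i) {
    spectral_centroid(candidates[[col]][[i]], candidates$fs_hz[i])
  }, 0)
  K <- result$K
  sizes <- tabulate(result$labels, K)
  mean_sc <- vapply(seq_len(K), function(k) {
    if (sizes[k] == 0) NA_real_ else mean(sc[result$labels == k])
  }, 0)
  if (any(sizes == 0)) {
    warn(sprintf("Empty cluster(s) %s mapped to artifact.",
                 paste(which(sizes == 0), collapse = ", ")))
  }
  if (anyDuplicated(stats::na.omit(mean_sc))) {
    warn("Tied cluster mean SCs; breaking ties by cluster size.")
  }
  classes4 <- c("HFO_FR", "HFO_R", "spike", "artifact")
  nonempty <- which(sizes > 0)
  ranked <- nonempty[order(-mean_sc[nonempty], -sizes[nonempty])]
  class_map <- rep("artifact", K)
  class_map[ranked] <- classes4[pmin(seq_along(ranked), 4L)]
  result$class_map <- class_map
  result$sc_hz <- sc
  result$class <- class_map[result$labels]
  result$is_hfo <- result$class %in% c("HFO_R", "HFO_FR")
  result
}
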