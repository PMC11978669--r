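two_clouds <- function(n = 30, gap = 20, d = 5, seed = 21) {
  hfocluster:::with_seed(seed, {
    rbind(matrix(rnorm(n * d), n, d),
          matrix(rnorm(n * d) + gap, n, d))
  })
}

partition_agrees <- function(labels, truth) {
  tab <- table(labels, truth)
  sum(apply(tab, 1, max)) == length(labels)
}

test_that("k-means recovers separated clouds exactly and handles K = 1", {
  X <- two_clouds()
  truth <- rep(1:2, each = 30)
  cl <- kmeans_cluster(X, K = 2, seed = 1)
  expect_true(partition_agrees(cl$labels, truth))
  expect_true(all(rowSums(cl$memberships) == 1))
  expect_true(all(cl$memberships %in% c(0, 1)))
  one <- kmeans_cluster(X, K = 1, seed = 1)
  expect_true(all(one$labels == 1))
  expect_equal(as.vector(one$centers), colMeans(X))
  expect_error(kmeans_cluster(X[1:3, ], K = 4), class = "hfo_config_error")
})

test_that("FCM memberships are a proper soft partition", {
  for (s in 1:5) {
    X <- matrix(rnorm(60), 20, 3) * s
    cl <- fcm_cluster(X, K = 3, seed = s)
    expect_equal(rowSums(cl$memberships), rep(1, 20), tolerance = 1e-9)
    expect_true(all(cl$memberships >= 0))
  }
})

test_that("FCM agrees with k-means on separated data", {
  X <- two_clouds()
  truth <- rep(1:2, each = 30)
  cl <- fcm_cluster(X, K = 2, seed = 3)
  expect_true(partition_agrees(cl$labels, truth))
  # fuzziness m -> 1+ approaches the hard partition
  hard <- fcm_cluster(X, K = 2, m = 1.05, seed = 3)
  expect_true(all(apply(hard$memberships, 1, max) > 0.99))
})

test_that("a point equidistant from two centroids splits its membership", {
  X <- rbind(matrix(rnorm(40, sd = 0.1) - 5, 20, 2),
             matrix(rnorm(40, sd = 0.1) + 5, 20, 2),
             c(0, 0))
  cl <- fcm_cluster(X, K = 2, seed = 4)
  expect_equal(unname(cl$memberships[41, ]), c(0.5, 0.5), tolerance = 0.05)
})

test_that("the diagonal GMM assigns confident responsibilities when separated", {
  X <- two_clouds(gap = 30)
  truth <- rep(1:2, each = 30)
  cl <- gmm_cluster(X, K = 2, seed = 5)
  expect_true(partition_agrees(cl$labels, truth))
  expect_true(all(apply(cl$memberships, 1, max) >= 0.99))
  expect_equal(rowSums(cl$memberships), rep(1, 60), tolerance = 1e-9)
})

test_that("the GMM matches mclust on low-dimensional separated data", {
  withr::local_package("mclust")
  X <- two_clouds(n = 40, gap = 12, d = 2, seed = 31)
  ours <- gmm_cluster(X, K = 2, seed = 6)
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_true(partition_agrees(ours$labels, ref$classification))
})

test_that("mean shift finds one global mode under a huge bandwidth", {
  X <- two_clouds()
  one <- meanshift_cluster(X, bandwidth = 1e4, reduce_to = NULL)
  expect_equal(one$K, 1)
  two <- meanshift_cluster(X, bandwidth = 5, reduce_to = NULL)
  expect_equal(two$K, 2)
  expect_true(partition_agrees(two$labels, rep(1:2, each = 30)))
  red <- meanshift_cluster(X, bandwidth = 0.5, reduce_to = 2)
  expect_lte(red$K, 2)
  expect_error(meanshift_cluster(X, bandwidth = 0),
               class = "hfo_config_error")
})

test_that("spectral centroid matches tone and mixture oracles", {
  fs <- 2560; n <- 384
  bin <- fs / n
  t <- (0:(n - 1)) / fs
  expect_equal(spectral_centroid(rep(0, n), fs), 0)
  expect_lt(spectral_centroid(rep(1, n), fs), bin)   # DC: energy at k = 0
  for (f in c(100, 150, 250, 400)) {
    expect_lt(abs(spectral_centroid(sin(2 * pi * f * t), fs) - f), bin)
  }
  mix <- sin(2 * pi * 100 * t) + sin(2 * pi * 400 * t)
  expect_lt(abs(spectral_centroid(mix, fs) - 250), bin)
  for (a in c(0.1, 1, 10)) {
    expect_equal(spectral_centroid(a * mix, fs), spectral_centroid(mix, fs),
                 tolerance = 1e-9)
  }
  expect_error(spectral_centroid(numeric(0), fs), class = "hfo_config_error")
})

sc_candidates <- function(freqs, per = 5, fs = 2560) {
  t <- (0:383) / fs
  tibble::tibble(
    fs_hz = fs,
    raw_window = lapply(rep(freqs, each = per),
                        function(f) sin(2 * pi * f * t)),
    filtered_window = lapply(rep(freqs, each = per),
                             function(f) sin(2 * pi * f * t))
  )
}

test_that("clusters are mapped to classes by descending mean SC", {
  cands <- sc_candidates(c(400, 150, 60, 30))
  cl <- hfocluster:::new_cluster_result(rep(1:4, each = 5),
                                        diag(4)[rep(1:4, each = 5), ],
                                        4, "manual")
  out <- assign_classes(cl, cands)
  expect_equal(out$class_map, c("HFO_FR", "HFO_R", "spike", "artifact"))
  expect_true(all(sort(out$class_map) == sort(c("HFO_FR", "HFO_R", "spike",
                                                "artifact"))))  # bijection
  expect_equal(out$is_hfo, rep(c(TRUE, TRUE, FALSE, FALSE), each = 5))
})

test_that("SC ties fall back to cluster size, larger ranked more HFO-like", {
  cands <- sc_candidates(c(150, 150), per = 6)
  labels <- rep(1:2, c(8, 4))   # same windows, unequal cluster sizes
  cl <- hfocluster:::new_cluster_result(labels, diag(2)[labels, ], 2, "manual")
  expect_warning(out <- assign_classes(cl, cands), "tie|Tie")
  expect_equal(out$class_map[1], "HFO_FR")
})

test_that("empty clusters are excluded and mapped to artifact", {
  cands <- sc_candidates(c(400, 150, 60))
  labels <- rep(1:3, each = 5)  # cluster 4 empty
  cl <- hfocluster:::new_cluster_result(labels, diag(4)[labels, ], 4, "manual")
  expect_warning(out <- assign_classes(cl, cands), "[Ee]mpty")
  expect_equal(out$class_map[4], "artifact")
  expect_equal(out$class_map[1:3], c("HFO_FR", "HFO_R", "spike"))
})
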