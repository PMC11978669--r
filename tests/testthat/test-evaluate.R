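test_that("confusion reproduces hand-computed metrics", {
  truth <- rep(c(TRUE, FALSE), c(100, 100))
  pred <- c(rep(TRUE, 94), rep(FALSE, 6), rep(FALSE, 92), rep(TRUE, 8))
  cm <- confusion(pred, truth)
  expect_equal(cm$tp, 94); expect_equal(cm$fn, 6)
  expect_equal(cm$tn, 92); expect_equal(cm$fp, 8)
  expect_equal(cm$accuracy, 93)
  expect_equal(cm$sensitivity, 94)
  expect_equal(cm$specificity, 92)
})

test_that("perfect prediction scores 100 everywhere", {
  truth <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  cm <- confusion(truth, truth)
  expect_equal(c(cm$accuracy, cm$sensitivity, cm$specificity),
               c(100, 100, 100))
})

test_that("zero-denominator metrics are missing, not zero", {
  cm <- confusion(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_true(is.na(cm$specificity))
  expect_equal(cm$sensitivity, 100)
  expect_error(confusion(TRUE, c(TRUE, FALSE)), class = "hfo_config_error")
})

test_that("confusion equals a brute-force count on random vectors", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    pred <- runif(n) > 0.5
    truth <- runif(n) > 0.5
    cm <- confusion(pred, truth)
    counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (j in seq_len(n)) {          # independent four-way counter
      counts[if (pred[j] && truth[j]) "tp"
             else if (!pred[j] && !truth[j]) "tn"
             else if (pred[j]) "fp" else "fn"] <-
        counts[if (pred[j] && truth[j]) "tp"
               else if (!pred[j] && !truth[j]) "tn"
               else if (pred[j]) "fp" else "fn"] + 1
    }
    expect_identical(c(cm$tp, cm$tn, cm$fp, cm$fn),
                     as.integer(unname(counts)))
  }
})

test_that("metrics are invariant to event ordering", {
  set.seed(32)
  pred <- runif(50) > 0.4; truth <- runif(50) > 0.5
  o <- sample(50)
  expect_equal(confusion(pred, truth), confusion(pred[o], truth[o]))
})

test_that("cross-validation folds are stratified, balanced and reproducible", {
  set.seed(33)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- rep(c(TRUE, FALSE), each = 100)
  m1 <- five_fold_cv(X, y, "knn", seed = 2)
  m2 <- five_fold_cv(X, y, "knn", seed = 2)
  expect_equal(m1, m2)
  folds <- attr(m1, "folds")
  sizes <- folds$tp + folds$tn + folds$fp + folds$fn
  expect_lte(max(sizes) - min(sizes), 2)   # 100+100 split 5 ways
  expect_error(five_fold_cv(X[1:103, ], y[c(1:3, 101:200)], "knn"),
               class = "hfo_stratification_error")
})

test_that("1-NN on duplicated points is perfect under cross-validation", {
  set.seed(34)
  base <- matrix(rnorm(40 * 3), 40, 3)
  X <- rbind(base, base)
  y <- rep(c(rep(TRUE, 20), rep(FALSE, 20)), 2)
  one_nn <- function(Xtr, ytr, Xte) {
    as.logical(as.integer(as.character(
      class::knn(Xtr, Xte, factor(as.integer(ytr)), k = 1))))
  }
  # folds chosen so each point's duplicate sits in a different fold: its
  # exact twin is then always available in the training split
  fold_id <- c(rep_len(1:5, 40), rep_len(c(2:5, 1), 40))
  cm <- five_fold_cv(X, y, one_nn, fold_id = fold_id)
  expect_equal(cm$accuracy, 100)
})

test_that("all supervised baselines separate linearly separable classes", {
  set.seed(35)
  X <- rbind(matrix(rnorm(60 * 3), 60, 3), matrix(rnorm(60 * 3) + 8, 60, 3))
  y <- rep(c(TRUE, FALSE), each = 60)
  for (m in c("knn", "svm_linear", "svm_poly", "svm_rbf")) {
    cm <- supervised_baseline(X, y, m, seed = 4)
    expect_gte(cm$accuracy, 99)
  }
  expect_error(supervised_baseline(X, rep(TRUE, 120), "knn"),
               class = "hfo_config_error")
})

test_that("permuted labels drop accuracy to the majority rate", {
  set.seed(36)
  X <- rbind(matrix(rnorm(200 * 3), 200, 3),
             matrix(rnorm(200 * 3) + 8, 200, 3))
  y <- sample(rep(c(TRUE, FALSE), each = 200))   # labels shuffled
  cm <- supervised_baseline(X, y, "svm_linear", seed = 5)
  expect_lt(abs(cm$accuracy - 50), 5)
})

test_that("the experiment grid reproduces the comparison-table structure", {
  w <- small_windows()
  grid <- default_grid()
  expect_equal(nrow(grid), 13)  # 4 supervised + 2 x 4 unsupervised + ablation
  res <- suppressWarnings(run_experiment_grid(
    w, grid, cvae = cvae_config(latent_dim = 5, epochs = 4, batch_size = 16,
                                filters = c(4, 8), seed = 7), seed = 1))
  expect_equal(nrow(res), nrow(grid))
  expect_true(all(c("representation", "model", "accuracy", "sensitivity",
                    "specificity") %in% names(res)))
  expect_true(all(is.finite(res$accuracy)))
  expect_error(run_experiment_grid(dplyr::select(w, -truth_hfo), grid),
               class = "hfo_config_error")
})

test_that("the latent/epoch sweep covers the requested grid", {
  w <- synth_candidate_windows(n_per_kind = 10, seed = 13)
  res <- suppressWarnings(run_latent_sweep(
    w, latent_dims = c(3, 4), epoch_grid = c(2, 3),
    base = cvae_config(latent_dim = 3, epochs = 2, batch_size = 8,
                       filters = c(2, 4), seed = 7), seed = 1))
  expect_equal(nrow(res), 4)
  expect_equal(sort(unique(res$latent_dim)), c(3, 4))
  expect_equal(sort(unique(res$epochs)), c(2, 3))
})

test_that("an event-free recording produces an empty report", {
  quiet <- ieeg_recording(matrix(0, 1, 2560 * 2), 2560)
  rep <- run_pipeline(quiet, pipeline_config())
  expect_s3_class(rep, "detection_report")
  expect_equal(nrow(rep$events), 0)
  expect_null(rep$metrics)
})

test_that("every candidate of a benchmark run receives a class label", {
  st <- small_benchmark()
  cfg <- pipeline_config(cvae = cvae_config(latent_dim = 8, epochs = 6,
                                            batch_size = 16,
                                            filters = c(4, 8), seed = 7))
  rep <- suppressWarnings(run_pipeline(st$bm$recording, cfg,
                                       annotations = st$bm$annotations))
  expect_equal(nrow(rep$events), nrow(st$candidates))
  expect_true(all(rep$events$class %in% c("HFO_FR", "HFO_R", "spike",
                                          "artifact")))
  expect_false(any(is.na(rep$events$sc_hz)))
  expect_s3_class(rep$metrics, "confusion_metrics")
  # tidiers expose the same content
  expect_equal(nrow(tidy(rep)), nrow(rep$events))
  expect_equal(glance(rep)$n_events, nrow(rep$events))
  expect_equal(nrow(tidy(rep$cvae_fit)), 6)
  expect_equal(glance(rep$cvae_fit)$latent_dim, 8)
  expect_equal(nrow(tidy(rep$cluster_result)), 4)
})

test_that("rerunning the grid under the same seeds reproduces every cell", {
  w <- synth_candidate_windows(n_per_kind = 8, seed = 17)
  grid <- tibble::tibble(representation = "RTFM",
                         model = c("kmeans", "fcm"))
  r1 <- suppressWarnings(run_experiment_grid(w, grid, seed = 9))
  r2 <- suppressWarnings(run_experiment_grid(w, grid, seed = 9))
  expect_equal(r1, r2)
})
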