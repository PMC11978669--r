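tiny_config <- function(epochs = 4, ...) {
  cvae_config(latent_dim = 5, epochs = epochs, batch_size = 16,
              filters = c(4, 8), seed = 7, ...)
}

test_that("configuration contracts are enforced", {
  expect_error(cvae_config(latent_dim = 0), class = "hfo_config_error")
  expect_error(cvae_config(epochs = 250), class = "hfo_config_error")
  expect_error(cvae_config(learning_rate = -1), class = "hfo_config_error")
})

test_that("model building is deterministic and shapes are as declared", {
  cfg <- tiny_config()
  m1 <- build_cvae(cfg); m2 <- build_cvae(cfg)
  expect_identical(m1$params, m2$params)
  X <- matrix(runif(4096 * 3), 4096, 3)
  enc <- hfocluster:::cvae_encode_fwd(m1, X)
  expect_equal(dim(enc$mu), c(5, 3))          # heads have latent_dim rows
  expect_equal(dim(enc$log_sigma), c(5, 3))
  dec <- hfocluster:::cvae_decode_fwd(m1, enc$mu)
  expect_equal(dim(dec$Xhat), c(4096, 3))     # 64 x 64 output per image
  expect_true(all(dec$Xhat > 0 & dec$Xhat < 1))
})

test_that("reparameterization has the stated degenerate and moment behaviour", {
  mu <- c(1.5, -2, 0.25)
  expect_equal(reparameterize(mu, rep(-1000, 3), 1), mu)
  expect_error(reparameterize(1:3, 1:2), class = "hfo_config_error")
  expect_identical(reparameterize(mu, c(0, 0, 0), 42),
                   reparameterize(mu, c(0, 0, 0), 42))
  z <- reparameterize(rep(0, 10000), rep(0, 10000), 5)
  expect_lt(abs(mean(z)), 3 / sqrt(10000))
  expect_lt(abs(var(z) - 1), 0.05)
})

test_that("the closed-form KL matches its known values", {
  expect_equal(kl_gaussian(0, 0), 0)
  expect_equal(kl_gaussian(rep(0, 7), rep(0, 7)), 0)
  expect_equal(kl_gaussian(1, 0), 0.5)        # per-dimension mu=1, sigma=1
  expect_equal(kl_gaussian(rep(1, 4), rep(0, 4)), 2)
  m <- matrix(c(0, 1), 1, 2)
  expect_equal(kl_gaussian(m, m * 0), c(0, 0.5))
})

test_that("elbo_loss rejects bad batches and is finite on good ones", {
  m <- build_cvae(tiny_config())
  good <- list(matrix(runif(4096), 64, 64))
  bad <- list(matrix(runif(4096) + 0.5, 64, 64))
  expect_error(elbo_loss(list(), m), class = "hfo_config_error")
  expect_error(elbo_loss(bad, m), class = "hfo_config_error")
  expect_true(is.finite(elbo_loss(good, m)))
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- cvae_config(latent_dim = 3, epochs = 1, batch_size = 4,
                     filters = c(2, 3), seed = 7)
  m <- build_cvae(cfg)
  set.seed(11)
  # move away from zero so no activation sits on a ReLU kink
  m$params <- lapply(m$params, function(w) w + rnorm(length(w), 0, 0.05))
  X <- matrix(runif(4096 * 4), 4096, 4)
  eps <- matrix(rnorm(3 * 4), 3)
  gr <- hfocluster:::cvae_grads(m, X, eps)
  loss_at <- function(m) {
    enc <- hfocluster:::cvae_encode_fwd(m, X)
    Z <- enc$mu + exp(enc$log_sigma) * eps
    dec <- hfocluster:::cvae_decode_fwd(m, Z)
    mean(colSums(hfocluster:::bce_from_logits(dec$u2, X)) +
           kl_gaussian(enc$mu, enc$log_sigma))
  }
  h <- 1e-5
  set.seed(12)
  for (nm in names(m$params)) {
    ii <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (i in ii) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      num <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      ana <- gr$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("training reduces the loss and is reproducible", {
  w <- small_windows()
  imgs <- small_rtfms()
  cfg <- tiny_config(epochs = 6)
  fit <- train_cvae(imgs, cfg)
  expect_equal(nrow(fit$loss_history), 6)
  expect_lt(fit$loss_history$loss[6], fit$loss_history$loss[1])
  fit2 <- train_cvae(imgs, cfg)
  expect_equal(fit$loss_history$loss, fit2$loss_history$loss)
  expect_identical(fit$model$params, fit2$model$params)
  expect_error(train_cvae(imgs[1:8], cfg), class = "hfo_config_error")
  expect_error(train_cvae(list(), cfg), class = "hfo_config_error")
})

test_that("reconstructions separate visually distinct classes", {
  w <- small_windows()
  imgs <- small_rtfms()
  fit <- train_cvae(imgs, tiny_config(epochs = 12))
  rec <- cvae_reconstruct(fit, imgs)
  expect_length(rec, length(imgs))
  expect_true(all(vapply(rec, function(r) all(dim(r) == c(64, 64)), TRUE)))
  expect_true(all(vapply(rec, function(r) min(r) >= 0 && max(r) <= 1, TRUE)))
  # within-class pixel distance below between-class distance (FR vs spike)
  fr <- which(w$kind == "fast_ripple")[1:8]
  sp <- which(w$kind == "spike")[1:8]
  X <- t(vapply(rec, as.vector, numeric(4096)))
  d <- as.matrix(dist(X[c(fr, sp), ]))
  within <- mean(d[1:8, 1:8][upper.tri(diag(8))])
  between <- mean(d[1:8, 9:16])
  expect_lt(within, between)
  # a trained model beats its seed initialisation on held-out images
  hold <- synth_candidate_windows(n_per_kind = 4, seed = 99)
  hrt <- lapply(hold$raw_window, window_rtfm, fs = hold$fs_hz[1])
  mse <- function(model) {
    rr <- hfocluster:::cvae_forward_images(model, hrt)
    mean(vapply(seq_along(hrt), function(i) mean((rr[[i]] - hrt[[i]])^2), 0))
  }
  expect_lt(mse(fit$model), mse(build_cvae(tiny_config(epochs = 12))))
  expect_error(cvae_reconstruct(build_cvae(tiny_config()), hrt),
               class = "hfo_config_error")
})

test_that("training loss is non-increasing once smoothed", {
  imgs <- small_rtfms()
  fit <- train_cvae(imgs, tiny_config(epochs = 16))
  sm <- stats::filter(fit$loss_history$loss, rep(1 / 8, 8), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.05 * abs(sm[-length(sm)])))
})
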