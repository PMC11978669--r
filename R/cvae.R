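#' Configuration for the convolutional variational auto-encoder
#'
#' The encoder applies two stride-2 3x3 convolutions (feature maps
#' 64 -> 32 -> 16) followed by two parallel linear heads producing the
#' posterior mean and log standard deviation of the latent code; the decoder
#' mirrors it with a linear layer and two transposed convolutions ending in a
#' sigmoid 64x64 output. Training minimises the negative evidence lower
#' bound: reconstruction negative log-likelihood plus the closed-form
#' KL divergence of the diagonal-Gaussian posterior from the unit-Gaussian
#' prior.
#'
#' @param latent_dim Latent dimensionality `l` (the ablation grid in the
#'   evaluation harness sweeps 10, 20, 30, 40, 50).
#' @param epochs Training epochs; capped at 200, where the training loss
#'   plateaus.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param filters Two integers: filter counts of the two convolution layers.
#' @param recon_loss `"bernoulli"` (per-pixel cross-entropy on `[0,1]`
#'   pixels, the default -- R-TFM pixels are naturally in `[0,1]`) or
#'   `"gaussian"` (squared error).
#' @param seed Integer seed determining initialisation, shuffling and the
#'   reparameterisation noise.
#' @return A list of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim = 50, epochs = 50, batch_size = 32,
                        learning_rate = 1e-3, filters = c(16, 32),
                        recon_loss = c("bernoulli", "gaussian"), seed = 1) {
  recon_loss <- match.arg(recon_loss)
  if (latent_dim <= 0) abort("`latent_dim` must be positive.",
                             class = "hfo_config_error")
  if (epochs > 200) abort("`epochs` must not exceed 200.",
                          class = "hfo_config_error")
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0) {
    abort("Invalid training hyper-parameters.", class = "hfo_config_error")
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 filters = as.integer(filters), recon_loss = recon_loss,
                 seed = as.integer(seed)),
            class = "cvae_config")
}

# ---- convolution plumbing (im2col / col2im via gather + rowsum) -----------

# geometry of a stride-2 "same"-padded convolution Cin x H x W -> F x Ho x Wo
conv_geom <- function(Cin, H, W, F, k = 3L, stride = 2L, pad = 1L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  L <- Ho * Wo
  # inner_idx: positions of the unpadded image inside the padded vector
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  one_ch <- (cc + pad - 1L) * Hp + (r + pad)
  inner_idx <- as.vector(outer(one_ch, (seq_len(Cin) - 1L) * Hp * Wp, "+"))
  # gather indices: for each output position l (col-major), the k*k*Cin patch
  l <- seq_len(L)
  ho <- (l - 1L) %% Ho + 1L
  wo <- (l - 1L) %/% Ho + 1L
  dr <- rep(seq_len(k), times = k)        # patch order: dr fastest, then dc,
  dc <- rep(seq_len(k), each = k)         # then channel
  patch_rc <- as.vector(outer((dc - 1L) * Hp + dr,
                              (seq_len(Cin) - 1L) * Hp * Wp, "+"))
  base <- ((wo - 1L) * stride) * Hp + ((ho - 1L) * stride)   # offset per l
  idx <- as.vector(outer(patch_rc, base, "+"))
  list(Cin = Cin, H = H, W = W, F = F, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, L = L, P = Cin * Hp * Wp,
       Ck2 = Cin * k * k, inner_idx = inner_idx, idx = idx,
       ug = sort(unique(idx)))
}

g_pad <- function(g, X) {
  Xp <- matrix(0, g$P, ncol(X))
  Xp[g$inner_idx, ] <- X
  Xp
}

g_im2col <- function(g, X) {
  Xc <- g_pad(g, X)[g$idx, , drop = FALSE]      # (Ck2*L) x B
  dim(Xc) <- c(g$Ck2, g$L * ncol(X))
  Xc
}

# conv forward: X (Cin*H*W x B) -> Y (L*F x B), returns cache for backward
conv_fwd <- function(g, X, W, b) {
  B <- ncol(X)
  Xc <- g_im2col(g, X)
  Y <- W %*% Xc + b                              # (F x L*B), bias recycles
  dim(Y) <- c(g$F, g$L, B)
  Y <- aperm(Y, c(2, 1, 3))
  dim(Y) <- c(g$L * g$F, B)
  list(Y = Y, Xc = Xc)
}

# reshape a (L*F x B) gradient/activation to the (F x L*B) matmul layout
to_fmat <- function(g, dOut) {
  B <- ncol(dOut)
  dim(dOut) <- c(g$L, g$F, B)
  dOut <- aperm(dOut, c(2, 1, 3))
  dim(dOut) <- c(g$F, g$L * B)
  dOut
}

# scatter-add a (Ck2 x L*B) column matrix back to image space (Cin*H*W x B)
g_col2im <- function(g, dXc, B) {
  dim(dXc) <- c(g$Ck2 * g$L, B)
  acc <- rowsum(dXc, group = g$idx)              # rows sorted by unique idx
  dXp <- matrix(0, g$P, B)
  dXp[g$ug, ] <- acc
  dXp[g$inner_idx, , drop = FALSE]
}

conv_bwd <- function(g, dOut, W, Xc) {
  B <- ncol(dOut)
  dY <- to_fmat(g, dOut)
  list(dW = dY %*% t(Xc),
       db = rowSums(dY),
       dX = g_col2im(g, t(W) %*% dY, B))
}

# transposed convolution ("deconv"): forward is the adjoint of conv_fwd with
# geometry g; maps (L*F x B) -> (Cin*H*W x B)
deconv_fwd <- function(g, X, V, cbias) {
  B <- ncol(X)
  out <- g_col2im(g, t(V) %*% to_fmat(g, X), B)
  out + rep(cbias, each = g$H * g$W)
}

deconv_bwd <- function(g, dOut, X, V) {
  B <- ncol(dOut)
  Gc <- g_im2col(g, dOut)
  dX <- V %*% Gc                                 # (F x L*B)
  dim(dX) <- c(g$F, g$L, B)
  dX <- aperm(dX, c(2, 1, 3))
  dim(dX) <- c(g$L * g$F, B)
  dOut3 <- dOut
  dim(dOut3) <- c(g$H * g$W, g$Cin, B)
  list(dV = to_fmat(g, X) %*% t(Gc),
       dc = apply(dOut3, 2, sum),
       dX = dX)
}

# ---- model ----------------------------------------------------------------

#' Build an untrained CVAE
#'
#' Allocates the network for 64x64 single-channel inputs with
#' He-initialised weights; the initialisation is fully determined by
#' `config$seed`.
#'
#' @param config A [cvae_config()].
#' @return An object of class `cvae_model`.
#' @export
build_cvae <- function(config) {
  stopifnot(inherits(config, "cvae_config"))
  f1 <- config$filters[1]; f2 <- config$filters[2]; l <- config$latent_dim
  g1 <- conv_geom(1L, 64L, 64L, f1)
  g2 <- conv_geom(f1, 32L, 32L, f2)
  nflat <- g2$L * f2                     # 16*16*f2
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  params <- with_seed(config$seed, list(
    W1 = he(f1, g1$Ck2, g1$Ck2), b1 = rep(0, f1),
    W2 = he(f2, g2$Ck2, g2$Ck2), b2 = rep(0, f2),
    Wmu = he(l, nflat, nflat) / 10, bmu = rep(0, l),
    Wls = he(l, nflat, nflat) / 10, bls = rep(0, l),
    Wd = he(nflat, l, l), bd = rep(0, nflat),
    V1 = he(f2, g2$Ck2, nflat), c1 = rep(0, f1),
    V2 = he(f1, g1$Ck2, g1$L * f1), c2 = rep(0, 1)
  ))
  structure(list(config = config, g1 = g1, g2 = g2, nflat = nflat,
                 params = params, trained = FALSE),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<cvae_model> latent %d, filters (%d, %d), %s parameters (%s)\n",
    x$config$latent_dim, x$config$filters[1], x$config$filters[2],
    format(np, big.mark = ","), if (x$trained) "trained" else "untrained"))
  invisible(x)
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

# encoder forward; X is 4096 x B
cvae_encode_fwd <- function(model, X) {
  p <- model$params
  c1 <- conv_fwd(model$g1, X, p$W1, p$b1); h1 <- relu(c1$Y)
  c2 <- conv_fwd(model$g2, h1, p$W2, p$b2); h2 <- relu(c2$Y)
  mu <- p$Wmu %*% h2 + p$bmu
  ls <- p$Wls %*% h2 + p$bls
  list(c1 = c1, h1 = h1, c2 = c2, h2 = h2, mu = mu, log_sigma = ls)
}

# decoder forward; Z is l x B; returns sigmoid pre-activation and output
cvae_decode_fwd <- function(model, Z) {
  p <- model$params
  d <- p$Wd %*% Z + p$bd; hd <- relu(d)
  u1 <- deconv_fwd(model$g2, hd, p$V1, p$c1); a1 <- relu(u1)
  u2 <- deconv_fwd(model$g1, a1, p$V2, p$c2)
  list(d = d, hd = hd, u1 = u1, a1 = a1, u2 = u2, Xhat = sigmoid(u2))
}

#' Reparameterization trick
#'
#' `z = mu + exp(log_sigma) * eps` with `eps ~ N(0, I)` drawn under
#' `noise_seed`, so the sampling step is differentiable in `mu` and
#' `log_sigma` and reproducible.
#'
#' @param mu,log_sigma Numeric vectors (or matrices, latent x batch) of equal
#'   dimension.
#' @param noise_seed Integer seed for the standard-normal draw.
#' @return `z`, same shape as `mu`.
#' @export
reparameterize <- function(mu, log_sigma, noise_seed = 1) {
  if (length(mu) != length(log_sigma)) {
    abort("`mu` and `log_sigma` must have equal length.",
          class = "hfo_config_error")
  }
  eps <- with_seed(noise_seed, rnorm(length(mu)))
  if (is.matrix(mu)) eps <- matrix(eps, nrow(mu), ncol(mu))
  mu + exp(log_sigma) * eps
}

#' Gaussian KL divergence (closed form)
#'
#' Per-dimension KL of `N(mu, sigma^2)` from `N(0, 1)`:
#' `0.5 * (mu^2 + sigma^2 - 1 - log sigma^2)`, summed over dimensions.
#'
#' @param mu,log_sigma Numeric vectors or matrices (latent x batch).
#' @return If matrices, one KL value per column; else a scalar.
#' @export
kl_gaussian <- function(mu, log_sigma) {
  per_dim <- 0.5 * (mu^2 + exp(2 * log_sigma) - 1 - 2 * log_sigma)
  if (is.matrix(mu)) colSums(per_dim) else sum(per_dim)
}

# numerically stable Bernoulli cross-entropy from logits a against targets x
bce_from_logits <- function(a, x) {
  pmax(a, 0) - a * x + log1p(exp(-abs(a)))
}

images_to_matrix <- function(images) {
  if (is.array(images) && length(dim(images)) == 3) {
    d <- dim(images)
    stopifnot(d[1] == 64, d[2] == 64)
    X <- images
    dim(X) <- c(4096, d[3])
    return(X)
  }
  if (is.matrix(images) && all(dim(images) == c(64, 64))) images <- list(images)
  stopifnot(is.list(images))
  vapply(images, function(im) {
    stopifnot(all(dim(im) == c(64, 64)))
    as.vector(im)
  }, numeric(4096))
}

#' Evidence-lower-bound loss of a batch
#'
#' Reconstruction negative log-likelihood plus closed-form KL divergence,
#' averaged over the batch. Pixels must lie in `[0, 1]`.
#'
#' @param images List of 64x64 matrices, or a 64x64xN array.
#' @param model A `cvae_model`.
#' @param noise_seed Seed for the reparameterisation draw.
#' @return Scalar loss (negative ELBO).
#' @export
elbo_loss <- function(images, model, noise_seed = 1) {
  X <- images_to_matrix(images)
  if (ncol(X) == 0) abort("Empty batch.", class = "hfo_config_error")
  if (min(X) < 0 || max(X) > 1) {
    abort("Pixels must lie in [0, 1].", class = "hfo_config_error")
  }
  enc <- cvae_encode_fwd(model, X)
  Z <- reparameterize(enc$mu, enc$log_sigma, noise_seed)
  dec <- cvae_decode_fwd(model, Z)
  recon <- if (model$config$recon_loss == "bernoulli") {
    colSums(bce_from_logits(dec$u2, X))
  } else {
    0.5 * colSums((dec$Xhat - X)^2)
  }
  mean(recon + kl_gaussian(enc$mu, enc$log_sigma))
}

# full forward/backward pass for one batch; returns loss and gradients
cvae_grads <- function(model, X, eps) {
  p <- model$params
  B <- ncol(X)
  enc <- cvae_encode_fwd(model, X)
  sig <- exp(enc$log_sigma)
  Z <- enc$mu + sig * eps
  dec <- cvae_decode_fwd(model, Z)

  if (model$config$recon_loss == "bernoulli") {
    recon <- colSums(bce_from_logits(dec$u2, X))
    dU2 <- (dec$Xhat - X) / B
  } else {
    recon <- 0.5 * colSums((dec$Xhat - X)^2)
    dU2 <- (dec$Xhat - X) * dec$Xhat * (1 - dec$Xhat) / B
  }
  loss <- mean(recon + kl_gaussian(enc$mu, enc$log_sigma))

  # decoder backward
  b2w <- deconv_bwd(model$g1, dU2, dec$a1, p$V2)
  dA1 <- b2w$dX * (dec$u1 > 0)
  b1w <- deconv_bwd(model$g2, dA1, dec$hd, p$V1)
  dHd <- b1w$dX * (dec$d > 0)
  dWd <- dHd %*% t(Z); dbd <- rowSums(dHd)
  dZ <- t(p$Wd) %*% dHd

  # KL gradients (mean over batch) + reparameterised reconstruction path
  dMu <- dZ + enc$mu / B
  dLs <- dZ * sig * eps + (sig^2 - 1) / B

  # encoder backward
  dH2 <- t(p$Wmu) %*% dMu + t(p$Wls) %*% dLs
  dWmu <- dMu %*% t(enc$h2); dbmu <- rowSums(dMu)
  dWls <- dLs %*% t(enc$h2); dbls <- rowSums(dLs)
  dC2 <- dH2 * (enc$c2$Y > 0)
  bw2 <- conv_bwd(model$g2, dC2, p$W2, enc$c2$Xc)
  dC1 <- bw2$dX * (enc$c1$Y > 0)
  bw1 <- conv_bwd(model$g1, dC1, p$W1, enc$c1$Xc)

  list(loss = loss, grads = list(
    W1 = bw1$dW, b1 = bw1$db, W2 = bw2$dW, b2 = bw2$db,
    Wmu = dWmu, bmu = dbmu, Wls = dWls, bls = dbls,
    Wd = dWd, bd = dbd,
    V1 = b1w$dV, c1 = b1w$dc, V2 = b2w$dV, c2 = b2w$dc
  ))
}

#' Train the CVAE on a set of R-TFM images
#'
#' Minimises the negative ELBO by minibatch Adam. Deterministic for a fixed
#' configuration: initialisation, shuffling and reparameterisation noise all
#' derive from `config$seed`.
#'
#' @param images List of 64x64 matrices (or 64x64xN array) with values in
#'   `[0, 1]`; at least `2 * batch_size` images.
#' @param config A [cvae_config()].
#' @param verbose Print the epoch losses?
#' @return An object of class `cvae_fit`: the trained `model`, a
#'   `loss_history` tibble (epoch, loss) and the config.
#' @export
train_cvae <- function(images, config = cvae_config(), verbose = FALSE) {
  X <- images_to_matrix(images)
  n <- ncol(X)
  if (n == 0) abort("Empty dataset.", class = "hfo_config_error")
  if (n < 2 * config$batch_size) {
    abort("Need at least 2 * batch_size images to train.",
          class = "hfo_config_error")
  }
  if (min(X) < 0 || max(X) > 1) {
    abort("Pixels must lie in [0, 1].", class = "hfo_config_error")
  }
  model <- build_cvae(config)
  p <- model$params
  mstate <- lapply(p, function(w) w * 0)
  vstate <- lapply(p, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsa <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  losses <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      bl <- 0; nb <- 0
      for (s in seq(1, n, by = config$batch_size)) {
        take <- ord[s:min(s + config$batch_size - 1L, n)]
        if (length(take) < 2) next
        Xb <- X[, take, drop = FALSE]
        eps <- matrix(rnorm(config$latent_dim * length(take)),
                      config$latent_dim)
        model$params <- p
        gr <- cvae_grads(model, Xb, eps)
        step <- step + 1L
        for (nm in names(p)) {
          g <- gr$grads[[nm]]
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
          mhat <- mstate[[nm]] / (1 - beta1^step)
          vhat <- vstate[[nm]] / (1 - beta2^step)
          p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + epsa)
        }
        bl <- bl + gr$loss; nb <- nb + 1
      }
      losses[ep] <- bl / nb
      if (verbose) message(sprintf("epoch %3d  loss %.3f", ep, losses[ep]))
    }
  })
  model$params <- p
  model$trained <- TRUE
  structure(list(model = model,
                 loss_history = tibble(epoch = seq_len(config$epochs),
                                       loss = losses),
                 config = config),
            class = "cvae_fit")
}

#' @export
print.cvae_fit <- function(x, ...) {
  cat(sprintf("<cvae_fit> %d epochs, final loss %.3f\n",
              nrow(x$loss_history),
              x$loss_history$loss[nrow(x$loss_history)]))
  print(x$model)
  invisible(x)
}

#' Encode images to latent codes
#'
#' Runs the encoder and (optionally) samples `z`; at inference the
#' deterministic posterior mean `z = mu` is used.
#'
#' @param model A `cvae_model` or `cvae_fit`.
#' @param images List of 64x64 matrices or 64x64xN array.
#' @param sample Draw `z` via [reparameterize()]? Default uses `z = mu`.
#' @param noise_seed Seed when sampling.
#' @return A list with matrices `mu`, `log_sigma`, `z` (latent x N).
#' @export
cvae_encode <- function(model, images, sample = FALSE, noise_seed = 1) {
  if (inherits(model, "cvae_fit")) model <- model$model
  X <- images_to_matrix(images)
  enc <- cvae_encode_fwd(model, X)
  z <- if (sample) reparameterize(enc$mu, enc$log_sigma, noise_seed) else enc$mu
  list(mu = enc$mu, log_sigma = enc$log_sigma, z = z)
}

#' Reconstruct R-TFM images through the trained CVAE
#'
#' Each image is encoded to its posterior mean and decoded back to a 64x64
#' image in `[0, 1]` -- the denoised reconstruction that is subsequently
#' clustered.
#'
#' @param fit A `cvae_fit` (or trained `cvae_model`).
#' @param images List of 64x64 matrices or 64x64xN array.
#' @param batch_size Images per forward chunk.
#' @return A list of 64x64 reconstruction matrices (same length/order as the
#'   input).
#' @export
cvae_reconstruct <- function(fit, images, batch_size = 64) {
  model <- if (inherits(fit, "cvae_fit")) fit$model else fit
  if (!inherits(model, "cvae_model")) {
    abort("`fit` must be a cvae_fit or cvae_model.", class = "hfo_config_error")
  }
  if (!model$trained) {
    abort("Model is untrained; call train_cvae() first.",
          class = "hfo_config_error")
  }
  cvae_forward_images(model, images, batch_size)
}

# shared forward machinery (also used on untrained models inside the tests)
cvae_forward_images <- function(model, images, batch_size = 64) {
  X <- images_to_matrix(images)
  n <- ncol(X)
  out <- vector("list", n)
  for (s in seq(1, n, by = batch_size)) {
    takes <- s:min(s + batch_size - 1L, n)
    enc <- cvae_encode_fwd(model, X[, takes, drop = FALSE])
    dec <- cvae_decode_fwd(model, enc$mu)
    for (j in seq_along(takes)) {
      im <- matrix(dec$Xhat[, j], 64, 64)
      class(im) <- c("rtfm", class(im))
      out[[takes[j]]] <- im
    }
  }
  out
}
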