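#' Train a fully connected shape auto-encoder
#'
#' A multilayer perceptron auto-encoder on flattened shape coordinates:
#' the encoder maps `3L -> hidden ... -> latent_dim` and the decoder
#' mirrors it back to `3L`.  Hidden layers use a `tanh` non-linearity; the
#' latent and output layers are linear.  Inputs are centred and globally
#' scaled before training, and the network is fitted by mini-batch Adam on
#' the mean squared reconstruction error.  A fixed seed gives reproducible
#' weights and latents.
#'
#' @param meshes a [mesh_config] or numeric `N x p` matrix.
#' @param latent_dim size of the latent code (`1 <= latent_dim < p`).
#' @param hidden integer vector of encoder hidden-layer widths (mirrored in
#'   the decoder).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param activation hidden-layer non-linearity, `"tanh"` or `"linear"`.
#' @param seed RNG seed for initialization and batching.
#' @return an object of class `shape_autoencoder` with the learned weights,
#'   normalization constants, and the per-epoch training `loss` path.
#' @export
train_autoencoder <- function(meshes, latent_dim, hidden = c(256L, 64L),
                              epochs = 200L, lr = 3e-3, batch_size = 32L,
                              activation = c("tanh", "linear"), seed = NULL) {
  activation <- match.arg(activation)
  X <- if (inherits(meshes, "mesh_config")) flatten_coords(meshes$coords) else as.matrix(meshes)
  p <- ncol(X); n <- nrow(X)
  if (latent_dim < 1L || latent_dim >= p)
    stop_arg("`latent_dim` must be in 1 .. (3L - 1)")
  mu <- colMeans(X)
  sdev <- sd(as.vector(sweep(X, 2L, mu)))
  if (sdev == 0) sdev <- 1
  Z <- sweep(X, 2L, mu) / sdev
  dims <- c(p, hidden, latent_dim, rev(hidden), p)
  nlayer <- length(dims) - 1L
  # tanh on hidden layers only; latent (layer length(hidden)+1) and output linear
  act <- rep(activation == "tanh", nlayer)
  act[length(hidden) + 1L] <- FALSE
  act[nlayer] <- FALSE
  with_seed(seed, {
    W <- lapply(seq_len(nlayer), function(l) {
      matrix(rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / (dims[l] + dims[l + 1L]))),
             dims[l], dims[l + 1L])
    })
    b <- lapply(seq_len(nlayer), function(l) numeric(dims[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_adam <- 0
    loss_path <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n)]
        x <- Z[rows, , drop = FALSE]
        # forward
        a <- vector("list", nlayer + 1L); a[[1L]] <- x
        for (l in seq_len(nlayer)) {
          z <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], `+`)
          a[[l + 1L]] <- if (act[l]) tanh(z) else z
        }
        err <- a[[nlayer + 1L]] - x
        ep_loss <- ep_loss + sum(err^2)
        # backward
        delta <- 2 * err / (length(rows) * p)
        for (l in rev(seq_len(nlayer))) {
          if (act[l]) delta <- delta * (1 - a[[l + 1L]]^2)
          gW <- crossprod(a[[l]], delta)
          gb <- colSums(delta)
          t_adam <- t_adam + 1
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^t_adam; corr2 <- 1 - beta2^t_adam
          W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
          if (l > 1L) delta <- delta %*% t(W[[l]])
        }
      }
      loss_path[ep] <- ep_loss / (n * p)
    }
    structure(list(W = W, b = b, act = act, dims = dims, mu = mu, sd = sdev,
                   latent_dim = latent_dim, n_encoder = length(hidden) + 1L,
                   activation = activation, loss = loss_path, seed = seed),
              class = "shape_autoencoder")
  })
}

#' @export
print.shape_autoencoder <- function(x, ...) {
  cat(sprintf("shape_autoencoder: %s, latent %d, final loss %.4g\n",
              paste(x$dims, collapse = "-"), x$latent_dim, tail(x$loss, 1)))
  invisible(x)
}

ae_forward <- function(model, Z, n_layers) {
  a <- Z
  for (l in seq_len(n_layers)) {
    a <- sweep(a %*% model$W[[l]], 2L, model$b[[l]], `+`)
    if (model$act[l]) a <- tanh(a)
  }
  a
}

#' Encode shapes to auto-encoder latent traits
#'
#' @param model a [train_autoencoder()] model.
#' @param meshes a [mesh_config] or numeric matrix with matching columns.
#' @return a `trait_set` of category `AE` with `latent_dim` traits.
#' @export
encode_latents <- function(model, meshes) {
  X <- if (inherits(meshes, "mesh_config")) flatten_coords(meshes$coords) else as.matrix(meshes)
  Z <- sweep(X, 2L, model$mu) / model$sd
  lat <- ae_forward(model, Z, model$n_encoder)
  trait_set(lat, "AE", trait_ids = sprintf("AE%03d", seq_len(ncol(lat))),
            provenance = data.frame(latent = seq_len(ncol(lat))),
            seed = model$seed)
}

#' Reconstruct shapes through the auto-encoder
#'
#' @inheritParams encode_latents
#' @return numeric matrix of reconstructed flattened coordinates, on the
#'   original scale.
#' @export
reconstruct_ae <- function(model, meshes) {
  X <- if (inherits(meshes, "mesh_config")) flatten_coords(meshes$coords) else as.matrix(meshes)
  Z <- sweep(X, 2L, model$mu) / model$sd
  out <- ae_forward(model, Z, length(model$W))
  sweep(out * model$sd, 2L, model$mu, `+`)
}
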