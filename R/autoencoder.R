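# Gated-recurrent sequence autoencoder for multichannel sensor transients.
#
# The encoder GRU consumes the sequence one time step at a time (each step is
# the vector of all channel values at that time); its final hidden state is
# the latent feature vector z. The decoder GRU is initialised from z, receives
# z as input at every step (repeat-vector scheme), and a linear readout maps
# its hidden states back to channel space in forward time order. Training
# minimises the mean squared reconstruction error over all D = channels x
# timesteps entries, by backpropagation through time with Adam updates.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# One GRU layer's parameters: input-to-gate W*, hidden-to-gate U*, biases b*.
gru_init <- function(n_in, n_hidden) {
  list(
    Wz = glorot(n_in, n_hidden), Uz = glorot(n_hidden, n_hidden), bz = numeric(n_hidden),
    Wr = glorot(n_in, n_hidden), Ur = glorot(n_hidden, n_hidden), br = numeric(n_hidden),
    Wh = glorot(n_in, n_hidden), Uh = glorot(n_hidden, n_hidden), bh = numeric(n_hidden)
  )
}

ae_init_params <- function(n_channels, latent_dim) {
  list(
    enc = gru_init(n_channels, latent_dim),
    dec = gru_init(latent_dim, latent_dim),
    V = glorot(latent_dim, n_channels),
    c = numeric(n_channels)
  )
}

# Run a GRU over a list of input matrices (each n x n_in), returning hidden
# states H[[t+1]] and gate caches needed for backprop.
gru_run <- function(p, X, H0) {
  Tt <- length(X)
  H <- vector("list", Tt + 1)
  Z <- R <- Hb <- vector("list", Tt)
  H[[1]] <- H0
  for (t in seq_len(Tt)) {
    Hprev <- H[[t]]
    Z[[t]] <- sigmoid(sweep(X[[t]] %*% p$Wz + Hprev %*% p$Uz, 2, p$bz, "+"))
    R[[t]] <- sigmoid(sweep(X[[t]] %*% p$Wr + Hprev %*% p$Ur, 2, p$br, "+"))
    Hb[[t]] <- tanh(sweep(X[[t]] %*% p$Wh + (R[[t]] * Hprev) %*% p$Uh, 2, p$bh, "+"))
    H[[t + 1]] <- (1 - Z[[t]]) * Hprev + Z[[t]] * Hb[[t]]
  }
  list(H = H, Z = Z, R = R, Hb = Hb)
}

# Backward step through one GRU cell. dH is the gradient w.r.t. H[[t+1]].
# Returns gradients w.r.t. the cell inputs plus parameter-gradient increments.
gru_cell_backward <- function(p, X_t, Hprev, Z, R, Hb, dH) {
  dZg <- dH * (Hb - Hprev)
  daz <- dZg * Z * (1 - Z)
  dHb <- dH * Z
  dah <- dHb * (1 - Hb^2)
  dHprev <- dH * (1 - Z)
  dRH <- dah %*% t(p$Uh)
  dR <- dRH * Hprev
  dar <- dR * R * (1 - R)
  dHprev <- dHprev + dRH * R + daz %*% t(p$Uz) + dar %*% t(p$Ur)
  dX <- daz %*% t(p$Wz) + dar %*% t(p$Wr) + dah %*% t(p$Wh)
  list(
    dHprev = dHprev, dX = dX,
    dWz = crossprod(X_t, daz), dUz = crossprod(Hprev, daz), dbz = colSums(daz),
    dWr = crossprod(X_t, dar), dUr = crossprod(Hprev, dar), dbr = colSums(dar),
    dWh = crossprod(X_t, dah), dUh = crossprod(R * Hprev, dah), dbh = colSums(dah)
  )
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

ae_forward <- function(par, X) {
  n <- nrow(X[[1]])
  Tt <- length(X)
  L <- ncol(par$enc$Wz)
  enc <- gru_run(par$enc, X, matrix(0, n, L))
  z <- enc$H[[Tt + 1]]
  Zin <- rep(list(z), Tt)
  dec <- gru_run(par$dec, Zin, z)
  Yhat <- purrr::map(dec$H[-1], function(h) sweep(h %*% par$V, 2, par$c, "+"))
  list(enc = enc, dec = dec, z = z, Zin = Zin, Yhat = Yhat)
}

ae_loss <- function(X, Yhat) {
  n <- nrow(X[[1]])
  D <- ncol(X[[1]]) * length(X)
  sum(purrr::map_dbl(seq_along(X), function(t) sum((Yhat[[t]] - X[[t]])^2))) / (n * D)
}

ae_backward <- function(par, X, fw) {
  Tt <- length(X)
  n <- nrow(X[[1]])
  D <- ncol(X[[1]]) * Tt
  L <- ncol(par$enc$Wz)
  g <- zero_like(par)
  # decoder + readout, backwards in time
  dHnext <- matrix(0, n, L)
  dzin <- matrix(0, n, L)
  for (t in Tt:1) {
    dY <- 2 * (fw$Yhat[[t]] - X[[t]]) / (n * D)
    g$V <- g$V + crossprod(fw$dec$H[[t + 1]], dY)
    g$c <- g$c + colSums(dY)
    dH <- dHnext + dY %*% t(par$V)
    bk <- gru_cell_backward(par$dec, fw$Zin[[t]], fw$dec$H[[t]],
                            fw$dec$Z[[t]], fw$dec$R[[t]], fw$dec$Hb[[t]], dH)
    for (nm in c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh")) {
      g$dec[[nm]] <- g$dec[[nm]] + bk[[paste0("d", nm)]]
    }
    dHnext <- bk$dHprev
    dzin <- dzin + bk$dX
  }
  dz <- dzin + dHnext # z feeds every decoder step and the initial state
  # encoder, backwards in time
  dHnext <- dz
  for (t in Tt:1) {
    bk <- gru_cell_backward(par$enc, X[[t]], fw$enc$H[[t]],
                            fw$enc$Z[[t]], fw$enc$R[[t]], fw$enc$Hb[[t]], dHnext)
    for (nm in c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh")) {
      g$enc[[nm]] <- g$enc[[nm]] + bk[[paste0("d", nm)]]
    }
    dHnext <- bk$dHprev
  }
  g
}

# Flatten/unflatten parameter trees for Adam state and gradient checking.
par_flatten <- function(p) unlist(p, use.names = FALSE)

par_unflatten <- function(template, v) {
  rapply(template, function(x) {
    k <- length(x)
    out <- v[seq_len(k)]
    v <<- v[-seq_len(k)]
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }, how = "replace")
}

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Convert a sample tibble / list of matrices into a time-major list of
# (n x channels) matrices, optionally standardised per channel.
signals_to_steps <- function(signals, center = NULL, scale = NULL) {
  shapes <- purrr::map(signals, dim)
  if (length(unique(purrr::map_chr(shapes, paste, collapse = "x"))) != 1) {
    abort("All samples must share the same (channels x timesteps) shape.",
          class = "msep_dimension_error")
  }
  n_channels <- shapes[[1]][1]
  n_timesteps <- shapes[[1]][2]
  arr <- array(unlist(signals), dim = c(n_channels, n_timesteps, length(signals)))
  if (!is.null(center)) {
    arr <- sweep(arr, 1, center, "-")
    arr <- sweep(arr, 1, scale, "/")
  }
  purrr::map(seq_len(n_timesteps), function(t) {
    t(matrix(arr[, t, , drop = FALSE], nrow = n_channels))
  })
}

as_signal_list <- function(samples) {
  if (is.data.frame(samples)) {
    if (!"signal" %in% names(samples)) {
      abort("`samples` must have a `signal` list-column.",
            class = "msep_dimension_error")
    }
    samples$signal
  } else if (is.list(samples) && all(purrr::map_lgl(samples, is.matrix))) {
    samples
  } else {
    abort("`samples` must be a sample tibble or a list of signal matrices.",
          class = "msep_dimension_error")
  }
}

#' Mean squared reconstruction error
#'
#' The autoencoder training objective: the mean of squared differences over
#' all D = channels x timesteps entries of a signal and its reconstruction.
#'
#' @param x Numeric matrix or vector (the original signal).
#' @param x_rec Reconstruction with the same shape.
#' @return A single non-negative number.
#' @examples
#' reconstruction_error(c(1, 2, 3), c(1, 2, 0)) # (0 + 0 + 9) / 3 = 3
#' @export
reconstruction_error <- function(x, x_rec) {
  if (!identical(dim(x), dim(x_rec)) || length(x) != length(x_rec)) {
    abort("`x` and `x_rec` must have identical shapes.",
          class = "msep_dimension_error")
  }
  mean((as.numeric(x) - as.numeric(x_rec))^2)
}

#' Fit a gated-recurrent sequence autoencoder
#'
#' Trains an encoder/decoder pair of GRU layers plus a linear readout to
#' reconstruct multichannel sensor transients, minimising the mean squared
#' reconstruction error by backpropagation through time with Adam. Channels
#' are standardised (zero mean, unit variance over the training set) before
#' fitting; encode/reconstruct apply and invert the same transform.
#'
#' @param samples Sample tibble (with a `signal` list-column) or list of
#'   equal-shape signal matrices; at least 2 samples.
#' @param latent_dim Dimension of the latent feature vector; must be smaller
#'   than channels x timesteps (it is a compression).
#' @param epochs Number of passes over the training set.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param seed Integer seed for parameter initialisation and shuffling.
#' @param verbose Print the per-epoch training loss.
#' @return An object of class `gru_autoencoder` with the trained parameters,
#'   per-channel standardisation constants and `training_history` (mean
#'   reconstruction error per epoch, on the standardised scale).
#' @export
fit_autoencoder <- function(samples, latent_dim = 8, epochs = 30,
                            learning_rate = 0.01, batch_size = 16, seed = 1L,
                            verbose = FALSE) {
  signals <- as_signal_list(samples)
  if (length(signals) < 2) {
    abort("Need at least 2 samples to fit the autoencoder.",
          class = "msep_config_error")
  }
  if (latent_dim < 1 || epochs < 1) {
    abort("`latent_dim` and `epochs` must be >= 1.", class = "msep_config_error")
  }
  shapes <- unique(purrr::map_chr(signals, function(s) paste(dim(s), collapse = "x")))
  if (length(shapes) != 1) {
    abort("All samples must share the same (channels x timesteps) shape.",
          class = "msep_dimension_error")
  }
  n_channels <- nrow(signals[[1]])
  n_timesteps <- ncol(signals[[1]])
  D <- n_channels * n_timesteps
  if (latent_dim >= D) {
    abort("`latent_dim` must be smaller than channels x timesteps.",
          class = "msep_config_error")
  }
  stacked <- do.call(cbind, signals) # channels x (timesteps * n)
  center <- rowMeans(stacked)
  scale <- apply(stacked, 1, sd)
  scale[scale == 0] <- 1
  steps <- signals_to_steps(signals, center, scale)
  n <- length(signals)

  set.seed(seed)
  par <- ae_init_params(n_channels, latent_dim)
  theta <- par_flatten(par)
  state <- list(t = 0, m = theta * 0, v = theta * 0)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    ep_loss <- 0
    for (b in batches) {
      Xb <- purrr::map(steps, function(m) m[b, , drop = FALSE])
      par <- par_unflatten(par, theta)
      fw <- ae_forward(par, Xb)
      ep_loss <- ep_loss + ae_loss(Xb, fw$Yhat) * length(b)
      g <- ae_backward(par, Xb, fw)
      upd <- adam_step(theta, par_flatten(g), state, learning_rate)
      theta <- upd$theta
      state <- upd$state
    }
    history[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %3d  mse %.6f", ep, history[ep]))
  }
  structure(
    list(
      params = par_unflatten(par, theta),
      latent_dim = latent_dim,
      input_dims = c(n_channels = n_channels, n_timesteps = n_timesteps),
      center = center, scale = scale,
      training_history = history,
      seed = seed
    ),
    class = "gru_autoencoder"
  )
}

check_fitted <- function(model) {
  if (!inherits(model, "gru_autoencoder") || is.null(model$params)) {
    abort("`model` must be a fitted gru_autoencoder.", class = "msep_state_error")
  }
}

check_sample_shape <- function(model, sig) {
  if (nrow(sig) != model$input_dims[["n_channels"]] ||
      ncol(sig) != model$input_dims[["n_timesteps"]]) {
    abort("Sample shape does not match the model's input dimensions.",
          class = "msep_dimension_error")
  }
}

#' Encode samples to latent feature vectors
#'
#' Runs the trained encoder over each sample; the final hidden state is the
#' latent feature vector. Deterministic given fixed model parameters.
#'
#' @param model A fitted [fit_autoencoder()] model.
#' @param samples A single signal matrix, a list of matrices, or a sample
#'   tibble.
#' @return For a single matrix, a numeric vector of length `latent_dim`; for
#'   a tibble, a tibble `sample_id`, `label`, `f1`..`f<latent_dim>`; for a
#'   list, a matrix of latent rows.
#' @export
encode <- function(model, samples) {
  check_fitted(model)
  if (is.matrix(samples)) {
    check_sample_shape(model, samples)
    return(drop(encode_matrix(model, list(samples))))
  }
  signals <- as_signal_list(samples)
  purrr::walk(signals, check_sample_shape, model = model)
  z <- encode_matrix(model, signals)
  if (is.data.frame(samples)) {
    colnames(z) <- paste0("f", seq_len(ncol(z)))
    dplyr::bind_cols(
      tibble(sample_id = samples$sample_id, label = samples$label),
      as_tibble(z)
    )
  } else {
    z
  }
}

encode_matrix <- function(model, signals) {
  steps <- signals_to_steps(signals, model$center, model$scale)
  L <- model$latent_dim
  enc <- gru_run(model$params$enc, steps, matrix(0, length(signals), L))
  enc$H[[length(steps) + 1]]
}

#' Reconstruct a sample through the autoencoder
#'
#' @param model A fitted [fit_autoencoder()] model.
#' @param sample A single signal matrix with the model's input shape.
#' @return The reconstructed signal matrix, in original (de-standardised)
#'   units.
#' @export
reconstruct <- function(model, sample) {
  check_fitted(model)
  check_sample_shape(model, sample)
  steps <- signals_to_steps(list(sample), model$center, model$scale)
  fw <- ae_forward(model$params, steps)
  rec <- do.call(rbind, purrr::map(fw$Yhat, as.numeric)) # timesteps x channels
  rec <- t(rec)
  rec <- sweep(rec, 1, model$scale, "*")
  sweep(rec, 1, model$center, "+")
}

#' Extract autoencoder features from a sample tibble
#'
#' Convenience wrapper around [encode()] returning a wide feature table
#' suitable for [train_pool()] and [run_msep()].
#'
#' @inheritParams encode
#' @return A tibble `sample_id`, `label`, `f1`..`f<latent_dim>`.
#' @export
extract_features <- function(model, samples) {
  if (!is.data.frame(samples)) {
    abort("`samples` must be a sample tibble.", class = "msep_dimension_error")
  }
  encode(model, samples)
}

#' @export
print.gru_autoencoder <- function(x, ...) {
  cat(sprintf(
    "<gru_autoencoder: %d channels x %d steps -> latent %d, %d epochs, final mse %.4g>\n",
    x$input_dims[["n_channels"]], x$input_dims[["n_timesteps"]],
    x$latent_dim, length(x$training_history),
    x$training_history[length(x$training_history)]
  ))
  invisible(x)
}

#' Save or load a fitted autoencoder
#'
#' @param model A fitted `gru_autoencoder`.
#' @param path File path for the serialised model.
#' @return `load_autoencoder()` returns the model; `save_autoencoder()`
#'   returns `path` invisibly.
#' @export
save_autoencoder <- function(model, path) {
  check_fitted(model)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  model <- readRDS(path)
  check_fitted(model)
  model
}
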