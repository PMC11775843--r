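#' Autoencoder training settings
#'
#' A small symmetric multilayer perceptron with a two-dimensional bottleneck
#' (4 -> 16 -> 8 -> 2 -> 8 -> 16 -> 4 by default), tanh activations on hidden
#' layers and a linear output, trained to minimize mean-squared
#' reconstruction error with the Adam optimizer. The two bottleneck
#' activations are the latent representation used for clustering.
#'
#' @param hidden Encoder hidden layer sizes (mirrored in the decoder).
#' @param latent_dim Bottleneck width; fixed at 2 for this analysis.
#' @param init Weight initialization: `"spectral"` (default) starts the
#'   network at its linear-regime optimum — the encoder implements the
#'   top-two principal-component projection through near-linear tanh units,
#'   the decoder its transpose — so training refines a geometry-preserving
#'   embedding instead of descending into an arbitrary nonlinear basin;
#'   `"xavier"` is standard random initialization.
#' @param bottleneck Activation of the bottleneck layer: `"linear"`
#'   (unbounded latent; default) or `"tanh"`.
#' @param weight_decay Decoupled L2 penalty applied to weights at each Adam
#'   step; discourages the high-curvature maps that fold cluster structure.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param val_fraction Fraction of points held out to monitor validation
#'   loss (0 disables early stopping).
#' @param patience Early-stopping patience, epochs without a material
#'   validation improvement.
#' @param min_delta Minimum relative validation-loss improvement that counts
#'   as progress for early stopping (default 1%). Slow residual drift of the
#'   reconstruction loss is not pursued: long past the initial fit it tends
#'   to buy reconstruction accuracy by bending the latent map, degrading the
#'   embedding's geometry.
#' @param seed Seed governing weight initialization and batch shuffling.
#' @return An object of class `autoencoder_config`.
#' @export
autoencoder_config <- function(hidden = c(16, 8), latent_dim = 2,
                               init = c("spectral", "xavier"),
                               bottleneck = c("linear", "tanh"),
                               weight_decay = 0,
                               epochs = 200, batch_size = 256,
                               learning_rate = 1e-3, val_fraction = 0.1,
                               patience = 10, min_delta = 0.01, seed = 1) {
  init <- match.arg(init)
  bottleneck <- match.arg(bottleneck)
  if (weight_decay < 0) stop("`weight_decay` must be >= 0", call. = FALSE)
  if (latent_dim != 2)
    stop("`latent_dim` is fixed at 2 for this analysis", call. = FALSE)
  if (any(hidden < 1)) stop("hidden sizes must be >= 1", call. = FALSE)
  check_scalar(epochs, "epochs", positive = TRUE)
  check_scalar(batch_size, "batch_size", positive = TRUE)
  check_scalar(learning_rate, "learning_rate", positive = TRUE)
  if (val_fraction < 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in [0, 1)", call. = FALSE)
  structure(list(hidden = as.integer(hidden), latent_dim = 2L,
                 init = init,
                 bottleneck = bottleneck, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction,
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "autoencoder_config")
}

# Forward pass through layers `from:to` of the network. Hidden layers are
# tanh; the output layer and the bottleneck layer are linear (an unbounded
# bottleneck leaves the latent geometry free instead of compressing cluster
# structure into the corners of (-1, 1)^2).
mlp_forward <- function(W, b, x, from = 1, to = length(W),
                        linear_layers = length(W)) {
  a <- x
  for (l in from:to) {
    z <- a %*% W[[l]]
    z <- z + rep(b[[l]], each = nrow(z))
    a <- if (l %in% linear_layers) z else tanh(z)
  }
  a
}

#' Train the reconstruction autoencoder
#'
#' @param x An n x 4 matrix of normalized clustering variables (mean about
#'   0, sd about 1; see [apply_normalizer()]).
#' @param cfg An [autoencoder_config()].
#' @return An object of class `encoder_model`: weights/biases for all
#'   layers, the layer sizes, and a training `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
train_autoencoder <- function(x, cfg = autoencoder_config()) {
  stopifnot(inherits(cfg, "autoencoder_config"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite values in training data",
                               call. = FALSE)
  if (nrow(x) < 100)
    stop("need at least 100 points to train the autoencoder", call. = FALSE)
  d <- ncol(x)
  sizes <- c(d, cfg$hidden, cfg$latent_dim, rev(cfg$hidden), d)
  with_seed(cfg$seed, train_autoencoder_impl(x, cfg, sizes))
}

train_autoencoder_impl <- function(x, cfg, sizes) {
  n <- nrow(x)
  L <- length(sizes) - 1
  n_enc <- L %/% 2
  d <- sizes[1]; q <- sizes[n_enc + 1]
  W <- vector("list", L); b <- vector("list", L)
  spectral_ok <- cfg$init == "spectral" && all(sizes[-(n_enc + 1)] >= d)
  if (spectral_ok) {
    # Spectral start: the network begins as the principal-component map
    # z = V' x, x_hat = V z, routed through tanh units in their linear
    # regime (inputs scaled by alpha so tanh(u) ~ u). This is the global
    # optimum of the *linear* autoencoder; training then refines from a
    # geometry-preserving basin rather than a random one.
    alpha <- 0.05
    # a tanh bottleneck needs its pre-activation kept in the linear regime
    beta <- if (identical(cfg$bottleneck, "tanh")) 0.25 else 1
    V <- svd(x, nu = 0, nv = d)$v[, seq_len(q), drop = FALSE]
    embed <- function(nr, nc, m) {
      out <- matrix(0, nr, nc)
      out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
      out
    }
    for (l in seq_len(L)) {
      W[[l]] <- if (l == 1) {
        alpha * embed(sizes[1], sizes[2], diag(d))
      } else if (l < n_enc) {
        embed(sizes[l], sizes[l + 1], diag(d))
      } else if (l == n_enc) {
        (beta / alpha) * embed(sizes[l], sizes[l + 1], V)
      } else if (l == n_enc + 1) {
        (alpha / beta) * embed(sizes[l], sizes[l + 1], t(V))
      } else if (l < L) {
        embed(sizes[l], sizes[l + 1], diag(d))
      } else {
        (1 / alpha) * embed(sizes[l], sizes[l + 1], diag(d))
      }
      # tiny symmetry-breaking noise so unused units can still learn
      W[[l]] <- W[[l]] + matrix(stats::rnorm(length(W[[l]]),
                                             sd = 1e-3 * max(abs(W[[l]]))),
                                nrow(W[[l]]))
      b[[l]] <- numeric(sizes[l + 1])
    }
  } else {
    # Xavier-uniform initialization
    for (l in seq_len(L)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
  }
  # validation split
  perm <- sample.int(n)
  n_val <- floor(cfg$val_fraction * n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer()
  train_idx <- if (n_val > 0) perm[-seq_len(n_val)] else perm
  xtr <- x[train_idx, , drop = FALSE]
  xval <- x[val_idx, , drop = FALSE]
  ntr <- nrow(xtr)
  # Adam state
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  lr <- cfg$learning_rate
  lin <- if (identical(cfg$bottleneck, "tanh")) L
         else c((L + 1) %/% 2, L)  # linear bottleneck and output
  mse <- function(xx) {
    if (nrow(xx) == 0) return(NA_real_)
    mean((mlp_forward(W, b, xx, linear_layers = lin) - xx)^2)
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; best_W <- W; best_b <- b; wait <- 0
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(ntr)
    batch_starts <- seq(1, ntr, by = cfg$batch_size)
    for (s in batch_starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1, ntr)]
      xb <- xtr[idx, , drop = FALSE]
      B <- nrow(xb)
      # forward, keeping activations
      act <- vector("list", L + 1)
      act[[1]] <- xb
      for (l in seq_len(L)) {
        z <- act[[l]] %*% W[[l]]
        z <- z + rep(b[[l]], each = B)
        act[[l + 1]] <- if (l %in% lin) z else tanh(z)
      }
      if (any(!is.finite(act[[L + 1]])))
        stop("autoencoder training diverged (non-finite loss)",
             call. = FALSE)
      # backward
      delta <- 2 * (act[[L + 1]] - xb) / (B * ncol(xb))
      for (l in L:1) {
        gW <- crossprod(act[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(W[[l]])
          # derivative of the previous layer's activation
          if (!((l - 1) %in% lin)) delta <- delta * (1 - act[[l]]^2)
        }
        step_l <- step + 1  # shared timestep per batch
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^step_l)
        vhW <- vW[[l]] / (1 - beta2^step_l)
        mhb <- mb[[l]] / (1 - beta1^step_l)
        vhb <- vb[[l]] / (1 - beta2^step_l)
        W[[l]] <- W[[l]] - lr * (mhW / (sqrt(vhW) + eps) +
                                   cfg$weight_decay * W[[l]])
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
      step <- step + 1
    }
    tr_loss <- mse(xtr)
    val_loss <- mse(xval)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tr_loss,
                                val_loss = val_loss))
    min_delta <- if (is.null(cfg$min_delta)) 0 else cfg$min_delta
    if (length(val_idx)) {
      if (val_loss < best_val * (1 - min_delta) - 1e-12) {
        best_val <- val_loss; best_W <- W; best_b <- b; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= cfg$patience) break
      }
    }
  }
  if (length(val_idx)) { W <- best_W; b <- best_b }
  structure(list(W = W, b = b, sizes = sizes,
                 n_encoder_layers = (length(sizes) - 1) %/% 2,
                 linear_layers = lin,
                 history = history, config = cfg),
            class = "encoder_model")
}

#' Encode points into the two-dimensional latent space
#'
#' Applies the encoder half of a trained autoencoder. Points must be
#' normalized with the same normalizer the model was trained on.
#'
#' @param model An `encoder_model` from [train_autoencoder()].
#' @param x An n x 4 matrix of normalized points.
#' @return An n x 2 matrix of latent coordinates.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "encoder_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$sizes[1])
    stop("expected ", model$sizes[1], "-dimensional input", call. = FALSE)
  mlp_forward(model$W, model$b, x, from = 1, to = model$n_encoder_layers,
              linear_layers = model$linear_layers)
}

#' Decode latent points back to the normalized variable space
#'
#' @param model An `encoder_model`.
#' @param z An n x 2 matrix of latent coordinates.
#' @return An n x 4 matrix of reconstructed normalized points.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "encoder_model"))
  z <- as.matrix(z)
  L <- length(model$W)
  if (ncol(z) != model$sizes[model$n_encoder_layers + 1])
    stop("expected ", model$sizes[model$n_encoder_layers + 1],
         "-dimensional latent input", call. = FALSE)
  mlp_forward(model$W, model$b, z, from = model$n_encoder_layers + 1,
              to = L, linear_layers = model$linear_layers)
}

#' @export
print.encoder_model <- function(x, ...) {
  cat("Autoencoder:", paste(x$sizes, collapse = " -> "), "\n")
  h <- x$history
  cat(sprintf("  trained %d epoch(s); final train MSE %.6f",
              nrow(h), h$train_loss[nrow(h)]))
  if (is.finite(h$val_loss[nrow(h)]))
    cat(sprintf(", val MSE %.6f", h$val_loss[nrow(h)]))
  cat("\n")
  invisible(x)
}
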