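# Autoencoder core ------------------------------------------------------------
#
# A symmetric funnel multilayer perceptron: 75-dimensional input, encoder
# 75 -> 75 -> 40 -> 24 -> 3, decoder mirrored back to 75. The 3-node
# bottleneck is the latent feature space (x, y, z). Hidden layers are ReLU;
# the bottleneck and output are sigmoid, so latent coordinates and
# reconstructions live in (0, 1), matching the [0, 1]-encoded inputs.
# Forward, backward and the Adam optimizer are implemented directly in
# matrix algebra: the encoder's analytic Jacobian (the attribution module)
# needs the internals anyway, and the network is small enough that R's
# BLAS-backed matrix products train it in seconds.

#' Autoencoder configuration
#'
#' @param layer_sizes_encoder Encoder layer widths, input first, bottleneck
#'   last. Default `c(75, 75, 40, 24, 3)`.
#' @param layer_sizes_decoder Decoder widths; defaults to the reverse of the
#'   encoder (symmetric architecture).
#' @param hidden_activation,bottleneck_activation,output_activation
#'   Activation names: `"relu"`, `"sigmoid"`, `"tanh"` or `"linear"`.
#' @param loss `"mse"` (mean squared reconstruction error, the default) or
#'   `"cross-entropy"` (elementwise binary cross-entropy).
#' @param learning_rate,beta1,beta2,eps Adam hyperparameters.
#' @param iterations_per_epoch Minibatch steps per epoch (default 60).
#' @param epochs Number of epochs (default 1; raise for a converged model).
#' @param batch_size Minibatch size; default `ceiling(n / iterations_per_epoch)`
#'   so one epoch is roughly one pass over the data.
#' @param seed Seed for weight initialization and minibatch shuffling.
#' @return A list of class `ae_config`.
#' @export
ae_config <- function(layer_sizes_encoder = c(75, 75, 40, 24, 3),
                      layer_sizes_decoder = rev(layer_sizes_encoder),
                      hidden_activation = "relu",
                      bottleneck_activation = "sigmoid",
                      output_activation = "sigmoid",
                      loss = c("mse", "cross-entropy"),
                      learning_rate = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      iterations_per_epoch = 60,
                      epochs = 1,
                      batch_size = NULL,
                      seed = 1L) {
  loss <- match.arg(loss)
  enc <- as.integer(layer_sizes_encoder)
  dec <- as.integer(layer_sizes_decoder)
  if (length(enc) < 2 || length(dec) < 2) abort("need at least one layer per half")
  if (enc[1] != dec[length(dec)]) abort("first encoder size must equal last decoder size")
  if (enc[length(enc)] != dec[1]) abort("encoder bottleneck must equal decoder input size")
  if (iterations_per_epoch < 1 || epochs < 1) abort("iterations_per_epoch and epochs must be >= 1")
  structure(list(
    layer_sizes_encoder = enc, layer_sizes_decoder = dec,
    hidden_activation = hidden_activation,
    bottleneck_activation = bottleneck_activation,
    output_activation = output_activation,
    loss = loss, learning_rate = learning_rate,
    beta1 = beta1, beta2 = beta2, eps = eps,
    iterations_per_epoch = as.integer(iterations_per_epoch),
    epochs = as.integer(epochs),
    batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
    seed = as.integer(seed)
  ), class = "ae_config")
}

activation_fun <- function(name) {
  switch(name,
    relu = function(z) pmax(z, 0),
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh = tanh,
    linear = identity,
    abort(paste0("unknown activation: ", name))
  )
}

# derivative as a function of (preactivation z, activation a)
activation_grad <- function(name) {
  switch(name,
    relu = function(z, a) (z > 0) * 1,
    sigmoid = function(z, a) a * (1 - a),
    tanh = function(z, a) 1 - a^2,
    linear = function(z, a) array(1, dim(z)),
    abort(paste0("unknown activation: ", name))
  )
}

# activation name per layer of the full stack
layer_activations <- function(config) {
  n_enc <- length(config$layer_sizes_encoder) - 1L
  n_dec <- length(config$layer_sizes_decoder) - 1L
  c(
    rep(config$hidden_activation, n_enc - 1L), config$bottleneck_activation,
    rep(config$hidden_activation, n_dec - 1L), config$output_activation
  )
}

#' Build an (untrained) autoencoder
#'
#' Initializes all weight matrices with a seeded Glorot-uniform scheme
#' (uniform on ±sqrt(6 / (fan_in + fan_out))) and zero biases;
#' deterministic per seed.
#'
#' @param config An [ae_config()].
#' @return An object of class `sle_autoencoder` with untrained weights.
#' @export
build_autoencoder <- function(config = ae_config()) {
  sizes <- c(config$layer_sizes_encoder,
             config$layer_sizes_decoder[-1])
  weights <- local_seed(derive_seed(config$seed, "init"), {
    purrr::map(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      fan_out <- sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      list(
        W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
        b = rep(0, fan_out)
      )
    })
  })
  structure(list(
    weights = weights,
    activations = layer_activations(config),
    n_encoder_layers = length(config$layer_sizes_encoder) - 1L,
    config = config,
    scaling = NULL,
    loss_history = numeric(0),
    trained = FALSE
  ), class = "sle_autoencoder")
}

# forward pass over layers 1..n_layers; X is n x d (rows = patients).
# Returns activations A (A[[1]] = input) and preactivations Z.
ae_forward <- function(model, X, n_layers = length(model$weights)) {
  A <- vector("list", n_layers + 1L)
  Z <- vector("list", n_layers)
  A[[1]] <- X
  for (l in seq_len(n_layers)) {
    Z[[l]] <- sweep(A[[l]] %*% model$weights[[l]]$W, 2, model$weights[[l]]$b, `+`)
    A[[l + 1L]] <- activation_fun(model$activations[l])(Z[[l]])
  }
  list(A = A, Z = Z)
}

ae_loss_value <- function(config, Y, X) {
  if (config$loss == "mse") {
    mean((Y - X)^2)
  } else {
    eps <- 1e-12
    -mean(X * log(Y + eps) + (1 - X) * log(1 - Y + eps))
  }
}

# gradient of the loss w.r.t. the output Y
ae_loss_grad <- function(config, Y, X) {
  if (config$loss == "mse") {
    2 * (Y - X) / length(Y)
  } else {
    eps <- 1e-12
    (-X / (Y + eps) + (1 - X) / (1 - Y + eps)) / length(Y)
  }
}

# full backward pass: gradients of the reconstruction loss w.r.t. every
# weight matrix and bias vector. Returns list(grads, loss).
ae_gradients <- function(model, X) {
  L <- length(model$weights)
  fwd <- ae_forward(model, X)
  Y <- fwd$A[[L + 1L]]
  loss <- ae_loss_value(model$config, Y, X)
  delta <- ae_loss_grad(model$config, Y, X) *
    activation_grad(model$activations[L])(fwd$Z[[L]], Y)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(
      W = crossprod(fwd$A[[l]], delta),
      b = colSums(delta)
    )
    if (l > 1L) {
      delta <- (delta %*% t(model$weights[[l]]$W)) *
        activation_grad(model$activations[l - 1L])(fwd$Z[[l - 1L]], fwd$A[[l]])
    }
  }
  list(grads = grads, loss = loss)
}

#' Train an autoencoder on an encoded feature matrix
#'
#' Runs `epochs * iterations_per_epoch` minibatch Adam steps minimizing the
#' reconstruction loss. Minibatches walk a seeded permutation of the rows,
#' so training is fully deterministic given the configuration seed. The
#' per-iteration training loss (evaluated on the minibatch before the
#' update) is appended to `loss_history`.
#'
#' Before the first step the output-layer bias is initialized at the
#' (inverse-activated) column means of the data, so optimization starts
#' from the best constant reconstruction and spends its steps on structure
#' rather than on mean-fitting; without this, the mean-fitting phase
#' drives the sigmoid bottleneck into saturation and the latent space
#' collapses. Disable with `init_output_bias = FALSE`.
#'
#' @param model An `sle_autoencoder` (from [build_autoencoder()]).
#' @param features Numeric matrix, patients x items, values in \[0, 1\]
#'   (e.g. from [encode_features()]), or a `cohort_matrix`.
#' @param epochs,iterations_per_epoch,batch_size,learning_rate Optional
#'   overrides of the stored configuration.
#' @param init_output_bias Initialize the output bias at the data means
#'   (default TRUE; only applied to an untrained model).
#' @return The trained model, with `loss_history` populated and the input
#'   scaling parameters attached when `features` carries them.
#' @export
ae_train <- function(model, features, epochs = NULL, iterations_per_epoch = NULL,
                     batch_size = NULL, learning_rate = NULL,
                     init_output_bias = TRUE) {
  if (inherits(features, "cohort_matrix")) features <- features$features
  config <- model$config
  config$epochs <- as.integer(epochs %||% config$epochs)
  config$iterations_per_epoch <- as.integer(iterations_per_epoch %||% config$iterations_per_epoch)
  config$batch_size <- batch_size %||% config$batch_size
  config$learning_rate <- learning_rate %||% config$learning_rate
  n <- nrow(features)
  d <- ncol(features)
  if (d != model$config$layer_sizes_encoder[1]) {
    abort(sprintf("feature matrix has %d columns but the network expects %d",
                  d, model$config$layer_sizes_encoder[1]))
  }
  bs <- as.integer(config$batch_size %||% ceiling(n / config$iterations_per_epoch))
  if (n < bs) {
    abort(sprintf("cohort has %d patients but batch_size is %d; use a smaller batch",
                  n, bs))
  }

  L <- length(model$weights)
  if (init_output_bias && !model$trained) {
    mu <- colMeans(features)
    model$weights[[L]]$b <- switch(
      model$activations[L],
      sigmoid = stats::qlogis(pmin(pmax(mu, 1e-3), 1 - 1e-3)),
      tanh = atanh(pmin(pmax(mu, -1 + 1e-3), 1 - 1e-3)),
      linear = mu,
      model$weights[[L]]$b
    )
  }
  m <- purrr::map(model$weights, ~list(W = .x$W * 0, b = .x$b * 0))
  v <- m
  t_step <- 0
  history <- numeric(config$epochs * config$iterations_per_epoch)

  local_seed(derive_seed(config$seed, "shuffle"), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      for (it in seq_len(config$iterations_per_epoch)) {
        pos <- ((it - 1L) * bs + seq_len(bs) - 1L) %% n + 1L
        batch <- features[perm[pos], , drop = FALSE]
        bw <- ae_gradients(model, batch)
        t_step <- t_step + 1
        history[t_step] <- bw$loss
        for (l in seq_len(L)) {
          for (p in c("W", "b")) {
            g <- bw$grads[[l]][[p]]
            m[[l]][[p]] <- config$beta1 * m[[l]][[p]] + (1 - config$beta1) * g
            v[[l]][[p]] <- config$beta2 * v[[l]][[p]] + (1 - config$beta2) * g^2
            mhat <- m[[l]][[p]] / (1 - config$beta1^t_step)
            vhat <- v[[l]][[p]] / (1 - config$beta2^t_step)
            model$weights[[l]][[p]] <- model$weights[[l]][[p]] -
              config$learning_rate * mhat / (sqrt(vhat) + config$eps)
          }
        }
      }
    }
  })
  model$loss_history <- history
  model$trained <- TRUE
  model$config <- config
  sc <- attr(features, "scaling")
  if (!is.null(sc)) model$scaling <- sc
  model
}

#' Encode patients into the latent feature space
#'
#' Forward pass through the encoder half only. Coordinates follow the raw
#' x/y/z axis convention; see [axis_convention()] for the reporting
#' feature-vector signs.
#'
#' @param model Trained `sle_autoencoder`.
#' @param features Feature matrix (patients x items) or `cohort_matrix`.
#' @return A `latent_embedding` tibble: `patient_id`, `x`, `y`, `z`.
#' @export
ae_encode <- function(model, features) {
  pid <- NULL
  if (inherits(features, "cohort_matrix")) {
    pid <- features$patient_ids
    features <- features$features
  }
  if (ncol(features) != model$config$layer_sizes_encoder[1]) {
    abort(sprintf("feature matrix has %d columns but the encoder expects %d",
                  ncol(features), model$config$layer_sizes_encoder[1]))
  }
  fwd <- ae_forward(model, features, n_layers = model$n_encoder_layers)
  latent <- fwd$A[[model$n_encoder_layers + 1L]]
  pid <- pid %||% attr(features, "patient_ids") %||% rownames(features) %||%
    as.character(seq_len(nrow(features)))
  out <- tibble::tibble(patient_id = pid,
                        x = as.vector(latent[, 1]),
                        y = as.vector(latent[, 2]),
                        z = as.vector(latent[, 3]))
  class(out) <- c("latent_embedding", class(out))
  attr(out, "convention") <- "raw-axes"
  out
}

#' Decode latent coordinates back to the feature space
#'
#' @param model Trained `sle_autoencoder`.
#' @param latent Numeric matrix (patients x bottleneck) or a
#'   `latent_embedding` tibble.
#' @return Reconstruction matrix, patients x items, values in (0, 1) with a
#'   sigmoid output.
#' @export
ae_decode <- function(model, latent) {
  if (inherits(latent, "latent_embedding")) {
    latent <- as.matrix(latent[, c("x", "y", "z")])
  }
  if (ncol(latent) != model$config$layer_sizes_decoder[1]) {
    abort(sprintf("latent matrix has %d columns but the decoder expects %d",
                  ncol(latent), model$config$layer_sizes_decoder[1]))
  }
  L <- length(model$weights)
  dec_model <- model
  dec_model$weights <- model$weights[(model$n_encoder_layers + 1L):L]
  dec_model$activations <- model$activations[(model$n_encoder_layers + 1L):L]
  fwd <- ae_forward(dec_model, latent)
  fwd$A[[length(fwd$A)]]
}

#' Reconstruction loss of a trained model on a cohort
#'
#' Mean over patients and items of the squared difference between input and
#' reconstruction (or binary cross-entropy, per the model's loss config).
#'
#' @param model Trained `sle_autoencoder`.
#' @param features Feature matrix or `cohort_matrix`.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(model, features) {
  if (inherits(features, "cohort_matrix")) features <- features$features
  fwd <- ae_forward(model, features)
  ae_loss_value(model$config, fwd$A[[length(fwd$A)]], features)
}

#' @export
print.sle_autoencoder <- function(x, ...) {
  sizes <- c(x$config$layer_sizes_encoder, x$config$layer_sizes_decoder[-1])
  cat(sprintf("<sle_autoencoder> %s (%s)\n",
              paste(sizes, collapse = "-"),
              if (x$trained) sprintf("trained, final loss %.4g", tail_loss(x)) else "untrained"))
  invisible(x)
}

tail_loss <- function(model) {
  if (length(model$loss_history) == 0) NA_real_ else model$loss_history[length(model$loss_history)]
}

#' Tidy an autoencoder: one row per layer
#'
#' @param x An `sle_autoencoder`.
#' @param ... Unused.
#' @return Tibble with layer index, half (encoder/decoder), input/output
#'   widths, activation and parameter count.
#' @method tidy sle_autoencoder
#' @export
tidy.sle_autoencoder <- function(x, ...) {
  purrr::map_dfr(seq_along(x$weights), function(l) {
    w <- x$weights[[l]]
    tibble::tibble(
      layer = l,
      half = if (l <= x$n_encoder_layers) "encoder" else "decoder",
      d_in = nrow(w$W), d_out = ncol(w$W),
      activation = x$activations[l],
      n_parameters = length(w$W) + length(w$b)
    )
  })
}

#' One-row summary of an autoencoder fit
#'
#' @param x An `sle_autoencoder`.
#' @param ... Unused.
#' @return Tibble with parameter count, training extent and the first/last
#'   training losses.
#' @method glance sle_autoencoder
#' @export
glance.sle_autoencoder <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(purrr::map_int(x$weights, ~length(.x$W) + length(.x$b))),
    n_layers = length(x$weights),
    bottleneck = x$config$layer_sizes_encoder[length(x$config$layer_sizes_encoder)],
    trained = x$trained,
    n_iterations = length(x$loss_history),
    initial_loss = if (length(x$loss_history)) x$loss_history[1] else NA_real_,
    final_loss = tail_loss(x)
  )
}
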