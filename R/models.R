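# The six hybrid architectures: specification, closed-form parameter
# accounting, building, training and prediction.
#
# Every model is Conv1D(128 filters, kernel 1, valid padding, softmax over
# the filter axis) -> MaxPool1D(pool 1, an identity kept for architecture
# parity) -> a recurrent stack -> Dropout(0.2) -> Dense(1, sigmoid). The
# two-layer hybrids use a single 64-unit recurrent layer; the three-layer
# hybrids use BiLSTM(64) -> X(32) -> X(16). All recurrent layers except the
# last return full sequences; the last returns its final hidden state.

#' Names of the six hybrid architectures
#' @export
MODEL_NAMES <- c("CBGG", "CBLL", "CBRR", "CNN-RNN", "CNN-LSTM", "CNN-GRU")

.rec_type_code <- c(rnn = 0L, lstm = 1L, gru2 = 2L, gru1 = 3L, bilstm = 4L)

.model_stacks <- function(name, gru_variant) {
  gru <- if (gru_variant == "double_bias") "gru2" else "gru1"
  switch(name,
    "CBGG" = list(kind = c("bilstm", gru, gru), units = c(64L, 32L, 16L)),
    "CBLL" = list(kind = c("bilstm", "lstm", "lstm"), units = c(64L, 32L, 16L)),
    "CBRR" = list(kind = c("bilstm", "rnn", "rnn"), units = c(64L, 32L, 16L)),
    "CNN-RNN" = list(kind = "rnn", units = 64L),
    "CNN-LSTM" = list(kind = "lstm", units = 64L),
    "CNN-GRU" = list(kind = gru, units = 64L),
    stop("unknown model name '", name, "'; expected one of: ",
         paste(MODEL_NAMES, collapse = ", "), call. = FALSE))
}

#' Specify one of the six hybrid architectures
#'
#' @param name One of `"CBGG"`, `"CBLL"`, `"CBRR"`, `"CNN-RNN"`,
#'   `"CNN-LSTM"`, `"CNN-GRU"` (underscores accepted).
#' @param gru_variant `"double_bias"` (separate input/recurrent bias
#'   vectors, reset gate applied after the recurrent product; the
#'   accounting under which the published totals of the two-layer hybrids
#'   are exact) or `"single_bias"` (the textbook single-bias cell).
#' @param conv_activation `"softmax"` (normalization across the 128 filter
#'   outputs at each time step; the literal published choice) or `"relu"`
#'   (ablation escape hatch).
#' @param conv_filters,dropout Front-end width and dropout rate.
#' @return An object of class `model_spec` with an ordered `layers` list.
#' @export
model_spec <- function(name, gru_variant = c("double_bias", "single_bias"),
                       conv_activation = c("softmax", "relu"),
                       conv_filters = 128L, dropout = 0.2) {
  name <- toupper(gsub("_", "-", name))
  if (!name %in% MODEL_NAMES)
    stop("unknown model name '", name, "'; expected one of: ",
         paste(MODEL_NAMES, collapse = ", "), call. = FALSE)
  gru_variant <- match.arg(gru_variant)
  conv_activation <- match.arg(conv_activation)
  stack <- .model_stacks(name, gru_variant)

  layers <- list(list(kind = "conv1d", filters = as.integer(conv_filters),
                      kernel = 1L, padding = "valid",
                      activation = conv_activation),
                 list(kind = "maxpool1d", pool = 1L))
  d <- as.integer(conv_filters)
  for (i in seq_along(stack$kind)) {
    u <- stack$units[i]
    layers[[length(layers) + 1L]] <- list(
      kind = stack$kind[i], units = u, input_dim = d,
      return_sequences = i < length(stack$kind))
    d <- if (stack$kind[i] == "bilstm") 2L * u else u
  }
  layers[[length(layers) + 1L]] <- list(kind = "dropout", rate = dropout)
  layers[[length(layers) + 1L]] <- list(kind = "dense", units = 1L,
                                        input_dim = d, activation = "sigmoid")
  structure(list(name = name, gru_variant = gru_variant,
                 conv_activation = conv_activation, layers = layers),
            class = "model_spec")
}

# per-layer trainable-parameter formulas (d inputs, u units):
#   conv1d kernel 1, univariate input: u*1*1 + u
#   simple RNN:              u * (d + u + 1)
#   LSTM:                4 * u * (d + u + 1)
#   BiLSTM:          2 * 4 * u * (d + u + 1)
#   GRU single bias:     3 * u * (d + u + 1)
#   GRU double bias:     3 * u * (d + u + 2)
#   dense:                   d + 1
.layer_params <- function(layer) {
  u <- layer$units
  d <- layer$input_dim
  switch(layer$kind,
    conv1d = layer$filters * 1L * 1L + layer$filters,
    maxpool1d = 0L, dropout = 0L,
    rnn = u * (d + u + 1L),
    lstm = 4L * u * (d + u + 1L),
    bilstm = 2L * 4L * u * (d + u + 1L),
    gru2 = 3L * u * (d + u + 2L),
    gru1 = 3L * u * (d + u + 1L),
    dense = d * u + u,
    stop("unknown layer kind '", layer$kind, "'", call. = FALSE))
}

#' Closed-form trainable-parameter count
#'
#' Sums the per-layer formulas over the spec's stack. Window length never
#' enters: the convolution has kernel 1 and recurrent parameters do not
#' depend on sequence length. Equals the number of weights held by a built
#' model.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  sum(vapply(spec$layers, .layer_params, integer(1)))
}

# C++-facing architecture descriptor
.arch_descriptor <- function(spec, window_length) {
  rec <- Filter(function(l) l$kind %in% names(.rec_type_code), spec$layers)
  list(conv_filters = spec$layers[[1]]$filters,
       conv_activation = spec$conv_activation,
       rec_type = unname(.rec_type_code[vapply(rec, `[[`, "", "kind")]),
       rec_units = vapply(rec, function(l) l$units, integer(1)),
       dropout = spec$layers[[length(spec$layers) - 1L]]$rate,
       window_length = as.integer(window_length))
}

.glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# recurrent kernels: one orthogonal u x u block per gate (the usual
# recurrent-initializer default; keeps hidden dynamics well conditioned)
.orthogonal_blocks <- function(u, gates) {
  do.call(cbind, lapply(seq_len(gates), function(g) {
    qr.Q(qr(matrix(stats::rnorm(u * u), u, u)))
  }))
}

# weight list in the positional order the compiled core expects; LSTM
# forget-gate biases start at 1 (common initialization, aids training)
.init_weights <- function(spec, window_length) {
  F <- spec$layers[[1]]$filters
  w <- list(conv_W = .glorot(1, F, 1, F), conv_b = matrix(0, 1, F))
  lstm_bias <- function(u) {
    b <- matrix(0, 1, 4 * u); b[1, (u + 1):(2 * u)] <- 1; b
  }
  for (layer in spec$layers) {
    if (!layer$kind %in% names(.rec_type_code)) next
    d <- layer$input_dim; u <- layer$units
    nm <- paste0(layer$kind, u)
    w2 <- switch(layer$kind,
      rnn = list(Wx = .glorot(d, u, d, u), Wh = .orthogonal_blocks(u, 1),
                 b = matrix(0, 1, u)),
      lstm = list(Wx = .glorot(d, 4 * u, d, u), Wh = .orthogonal_blocks(u, 4),
                  b = lstm_bias(u)),
      gru2 = list(Wx = .glorot(d, 3 * u, d, u), Wh = .orthogonal_blocks(u, 3),
                  bx = matrix(0, 1, 3 * u), bh = matrix(0, 1, 3 * u)),
      gru1 = list(Wx = .glorot(d, 3 * u, d, u), Wh = .orthogonal_blocks(u, 3),
                  b = matrix(0, 1, 3 * u)),
      bilstm = list(fWx = .glorot(d, 4 * u, d, u), fWh = .orthogonal_blocks(u, 4),
                    fb = lstm_bias(u),
                    bWx = .glorot(d, 4 * u, d, u), bWh = .orthogonal_blocks(u, 4),
                    bb = lstm_bias(u)))
    names(w2) <- paste0(nm, "_", names(w2))
    w <- c(w, w2)
  }
  d_out <- spec$layers[[length(spec$layers)]]$input_dim
  c(w, list(dense_w = .glorot(d_out, 1, d_out, 1), dense_b = matrix(0, 1, 1)))
}

#' Build a trainable model handle
#'
#' @param spec A [model_spec()].
#' @param window_length Input window length in samples.
#' @return An object of class `hybrid_model`; unfitted (weights are
#'   initialized at training time from the training seed).
#' @export
build_model <- function(spec, window_length = 128L) {
  stopifnot(inherits(spec, "model_spec"))
  window_length <- as.integer(window_length)
  if (window_length < 1L) stop("window_length must be >= 1", call. = FALSE)
  structure(
    list(spec = spec, window_length = window_length,
         arch = .arch_descriptor(spec, window_length),
         weights = NULL, fitted = FALSE, trace = NULL),
    class = "hybrid_model")
}

#' Training configuration
#'
#' Binary cross-entropy loss under Adam, as published: 200 epochs, batch
#' size 50. The Adam step size (not stated in the source protocol) uses
#' the conventional default 1e-3 with beta1 = 0.9, beta2 = 0.999.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param seed Integer seed driving weight initialization, shuffling and
#'   dropout.
#' @param learning_rate Adam step size.
#' @param classification_threshold Probability cut for the accuracy metric
#'   and [predict.hybrid_model()]; ties (p equal to the threshold) map to
#'   the stress class.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 50L, seed = 1L,
                         learning_rate = 1e-3,
                         classification_threshold = 0.5) {
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (classification_threshold <= 0 || classification_threshold >= 1)
    stop("classification_threshold must lie in (0, 1)", call. = FALSE)
  structure(list(loss = "binary_crossentropy", optimizer = "adam",
                 epochs = epochs, batch_size = batch_size,
                 seed = as.integer(seed), learning_rate = learning_rate,
                 classification_threshold = classification_threshold),
            class = "train_config")
}

.as_xy <- function(samples, idx = NULL) {
  if (inherits(samples, "window_dataset")) {
    X <- samples$values; y <- samples$meta$label
  } else if (is.list(samples) && !is.null(samples$x)) {
    X <- samples$x; y <- samples$y
  } else stop("samples must be a window_dataset or list(x =, y =)", call. = FALSE)
  if (!is.null(idx)) { X <- X[idx, , drop = FALSE]; y <- y[idx] }
  list(x = X, y = as.numeric(y))
}

#' Train a hybrid model
#'
#' Deterministic given `config$seed` (single-threaded compiled training
#' loop; weight initialization, epoch shuffling and dropout all derive from
#' the seed). A non-finite loss aborts with a divergence error.
#'
#' @param model A `hybrid_model` from [build_model()].
#' @param train_samples,val_samples A `window_dataset` (or
#'   `list(x = matrix, y = labels)`); validation may be `NULL`.
#' @param config A [train_config()].
#' @return The fitted `hybrid_model`; the per-epoch convergence trace is a
#'   data frame in `$trace` (columns epoch, train_loss, train_acc,
#'   val_loss, val_acc).
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "hybrid_model"), inherits(config, "train_config"))
  tr <- .as_xy(train_samples)
  if (nrow(tr$x) == 0L) stop("empty training set", call. = FALSE)
  if (length(unique(tr$y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  if (ncol(tr$x) != model$window_length)
    stop("window length mismatch: model expects ", model$window_length,
         ", data has ", ncol(tr$x), call. = FALSE)

  va <- if (!is.null(val_samples)) .as_xy(val_samples) else NULL

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  weights <- .init_weights(model$spec, model$window_length)

  fit <- nn_train_cpp(weights, model$arch, tr$x, tr$y,
                      if (is.null(va)) NULL else va$x,
                      if (is.null(va)) NULL else va$y,
                      config$epochs, config$batch_size,
                      config$learning_rate, config$seed,
                      config$classification_threshold)

  model$weights <- fit$weights
  model$fitted <- TRUE
  model$train_config <- config
  model$trace <- data.frame(
    epoch = seq_len(config$epochs),
    train_loss = as.numeric(fit$train_loss),
    train_acc = as.numeric(fit$train_acc),
    val_loss = as.numeric(fit$val_loss),
    val_acc = as.numeric(fit$val_acc))
  model
}

#' Predict stress probabilities and labels
#'
#' @param object A fitted `hybrid_model`.
#' @param newdata A `window_dataset` or numeric matrix (one window per row).
#' @param threshold Probability threshold; `p >= threshold` maps to label 1
#'   (stress), so a tie goes to the stress class.
#' @param ... Unused.
#' @return List with `probabilities` and integer `labels`.
#' @export
predict.hybrid_model <- function(object, newdata, threshold = 0.5, ...) {
  if (!isTRUE(object$fitted)) stop("model is not fitted", call. = FALSE)
  X <- if (inherits(newdata, "window_dataset")) newdata$values else as.matrix(newdata)
  if (ncol(X) != object$window_length)
    stop("window length mismatch", call. = FALSE)
  prob <- as.numeric(nn_predict_cpp(object$weights, object$arch, X))
  list(probabilities = prob, labels = as.integer(prob >= threshold))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, " (GRU: ", x$gru_variant, ", conv: ",
      x$conv_activation, ")\n", sep = "")
  for (l in x$layers) {
    extra <- switch(l$kind,
      conv1d = sprintf("filters=%d kernel=%d %s", l$filters, l$kernel, l$activation),
      maxpool1d = sprintf("pool=%d", l$pool),
      dropout = sprintf("rate=%g", l$rate),
      dense = sprintf("units=%d sigmoid", l$units),
      sprintf("units=%d%s", l$units,
              if (isTRUE(l$return_sequences)) " (sequences)" else " (final state)"))
    cat("  ", format(l$kind, width = 10), extra, "\n", sep = "")
  }
  cat("  total parameters: ", count_parameters(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("<hybrid_model> ", x$spec$name, ", window ", x$window_length,
      if (isTRUE(x$fitted)) ", fitted" else ", unfitted", "\n", sep = "")
  invisible(x)
}
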