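#' Model configuration
#'
#' Hyperparameters shared by both decoder variants. Defaults follow the
#' study recipe: 16 latent sources, temporal filters of 14 samples (112 ms
#' at 125 Hz), non-overlapping max-pooling over 4 adjacent samples, Adam
#' with batch size 100 and learning rate 3e-4 minimising binary
#' cross-entropy, dropout 0.5 before the dense layer and an l1 penalty of
#' 3e-4 on both convolutional layers.
#'
#' @param k number of latent sources.
#' @param l_filt temporal filter length in samples.
#' @param pool max-pooling width and stride.
#' @param dropout_rate dropout probability before the dense layer.
#' @param l1_penalty l1 scale on spatial and temporal convolution weights.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (capped at the training-set size).
#' @param max_iterations number of minibatch updates.
#' @param seed integer seed controlling initialisation, batch order and
#'   dropout.
#' @return A `model_config` object.
#' @export
model_config <- function(k = 16, l_filt = 14, pool = 4, dropout_rate = 0.5,
                         l1_penalty = 3e-4, learning_rate = 3e-4,
                         batch_size = 100, max_iterations = 1000, seed = 1) {
  stopifnot(k >= 1, l_filt >= 1, pool >= 1, learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1, l1_penalty >= 0,
            batch_size >= 1, max_iterations >= 1)
  structure(list(k = as.integer(k), l_filt = as.integer(l_filt),
                 pool = as.integer(pool), dropout_rate = dropout_rate,
                 l1_penalty = l1_penalty, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)), class = "model_config")
}

#' Build an untrained decoder
#'
#' Lays out the network for the requested variant: a linear spatial
#' convolution projecting the channels onto `k` latent-source time courses,
#' a temporal layer ("same" padding, so the convolved length equals the
#' input length), ReLU, non-overlapping max-pooling of width `pool`, dropout
#' and a single dense softmax layer over the two classes. The `lf` variant
#' filters each latent source with its own length-`l_filt` FIR filter (no
#' cross-source mixing); the `var` variant lets every filtered output depend
#' on all `k` sources (a vector-autoregressive temporal layer with `k` times
#' as many temporal weights). Weights are initialised with seed-controlled
#' small Gaussians (Glorot scaling).
#'
#' @param variant `"lf"` or `"var"`.
#' @param n_channels input channel count.
#' @param n_times input timepoints per trial (must exceed `l_filt`).
#' @param config a [model_config()].
#' @return An untrained `fixdecode_model`.
#' @export
build_model <- function(variant = c("lf", "var"), n_channels, n_times,
                        config = model_config()) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "model_config"))
  if (n_times <= config$l_filt)
    stop("invalid-architecture: n_times must exceed l_filt")
  k <- config$k
  set.seed(config$seed)
  glorot <- function(dims, fan_in, fan_out)
    array(rnorm(prod(dims), sd = sqrt(2 / (fan_in + fan_out))), dims)
  W <- glorot(c(n_channels, k), n_channels, k)
  temporal <- if (variant == "lf") {
    glorot(c(k, config$l_filt), config$l_filt, 1)
  } else {
    glorot(c(k, k, config$l_filt), k * config$l_filt, k)
  }
  n_pooled <- n_times %/% config$pool
  # near-zero output layer: trained weight magnitude then reflects each
  # latent source's contribution rather than the initialisation scale
  D <- array(rnorm(k * n_pooled * 2, sd = 0.01), c(k * n_pooled, 2))
  structure(list(variant = variant, W = W, temporal_filters = temporal,
                 D = D, bias = c(0, 0), config = config,
                 n_channels = as.integer(n_channels),
                 n_times = as.integer(n_times),
                 n_pooled = as.integer(n_pooled),
                 trace = NULL, trained = FALSE),
            class = "fixdecode_model")
}

#' @export
print.fixdecode_model <- function(x, ...) {
  cat(sprintf("%s decoder: %d channels -> %d latent sources, %d timepoints (%d pooled), %s\n",
              toupper(x$variant), x$n_channels, x$config$k, x$n_times,
              x$n_pooled, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

.as_cube <- function(epochs) aperm(epochs$data, c(2, 3, 1))

.check_shapes <- function(model, epochs) {
  d <- dim(epochs$data)
  if (d[2] != model$n_channels || d[3] != model$n_times)
    stop(sprintf("shape mismatch: model expects %d x %d, data is %d x %d",
                 model$n_channels, model$n_times, d[2], d[3]))
}

#' Train a decoder
#'
#' Runs `max_iterations` Adam minibatch updates minimising binary
#' cross-entropy (plus the l1 penalty on convolutional weights), recording
#' the validation ROC AUC after every update into the model's `trace`.
#' Deterministic given the configuration seed.
#'
#' @param model an untrained (or previously trained) `fixdecode_model`.
#' @param train_epochs labeled [epoch_set()] used for the updates.
#' @param val_epochs labeled `epoch_set` scored for the trace; pass `NULL`
#'   to skip trace evaluation (the trace is then all `NA`).
#' @param config optional [model_config()] overriding the model's own.
#' @return The trained model with updated weights and `trace`.
#' @export
train_model <- function(model, train_epochs, val_epochs = NULL,
                        config = NULL) {
  stopifnot(inherits(model, "fixdecode_model"))
  if (is.null(config)) config <- model$config
  .check_shapes(model, train_epochs)
  y <- as.integer(train_epochs$labels)
  if (is.null(y)) stop("degenerate-training: training epochs have no labels")
  if (length(unique(y)) < 2)
    stop("degenerate-training: training set contains a single class")
  if (is.null(val_epochs)) {
    Xval <- array(0, c(model$n_channels, model$n_times, 0))
    yval <- integer(0)
  } else {
    .check_shapes(model, val_epochs)
    Xval <- .as_cube(val_epochs)
    yval <- as.integer(val_epochs$labels)
  }
  set.seed(config$seed)
  fit <- cnn_train_cpp(.as_cube(train_epochs), y, Xval, yval,
                       model$W, model$temporal_filters, model$D, model$bias,
                       model$variant == "var", config$l_filt, config$pool,
                       config$learning_rate, config$batch_size,
                       config$max_iterations, config$dropout_rate,
                       config$l1_penalty)
  model$W <- fit$W
  model$temporal_filters <- if (model$variant == "var") fit$F else
    matrix(fit$F, nrow = config$k)
  model$D <- fit$D
  model$bias <- as.numeric(fit$b)
  model$trace <- as.numeric(fit$trace)
  model$trained <- TRUE
  model$config <- config
  model
}

#' Predict class probabilities
#'
#' Forward pass without dropout; each row is the softmax pair
#' (spontaneous, voluntary) and sums to 1.
#'
#' @param model a `fixdecode_model`.
#' @param epochs an [epoch_set()] with matching channel/time dimensions.
#' @return numeric matrix, trials x 2.
#' @export
predict_proba <- function(model, epochs) {
  stopifnot(inherits(model, "fixdecode_model"))
  .check_shapes(model, epochs)
  p <- cnn_predict_cpp(.as_cube(epochs), model$W, model$temporal_filters,
                       model$D, model$bias, model$variant == "var",
                       model$config$l_filt, model$config$pool)
  colnames(p) <- c("spontaneous", "voluntary")
  p
}

#' @export
predict.fixdecode_model <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' Output weights as a pooled-time x sources x classes tensor
#'
#' Rearranges the dense layer into the `t x k x 2` tensor used by the
#' latent-source contribution analysis (`t` = pooled timepoints).
#'
#' @param model a `fixdecode_model`.
#' @return numeric array of dimension `n_pooled x k x 2`.
#' @export
output_weight_tensor <- function(model) {
  stopifnot(inherits(model, "fixdecode_model"))
  k <- model$config$k
  p <- model$n_pooled
  w <- array(NA_real_, c(p, k, 2))
  for (ci in 1:2)
    w[, , ci] <- t(matrix(model$D[, ci], nrow = k, ncol = p))
  w
}
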