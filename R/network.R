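# Sequence classifier: bidirectional LSTM (outputs of the two directions
# concatenated) -> dropout -> LSTM (last state) -> dense ReLU -> softmax,
# trained with RMSprop on categorical cross-entropy.

#' Network specification
#'
#' Architecture and training hyperparameters. Defaults follow the reference
#' setting: 128 Bi-LSTM units per direction, dropout 0.3, a 64-unit LSTM,
#' a 128-unit dense layer, RMSprop at learning rate 0.001, 46 epochs
#' (55 for the 32-channel 2-class configuration), batch size 32.
#'
#' @param input_size features per window (17 or 19 for the named subsets).
#' @param n_classes number of output classes (>= 2).
#' @param seq_len windows per trial (default 29).
#' @param bilstm_units,lstm_units,dense_units layer widths.
#' @param dropout dropout fraction in `[0, 1)` after the Bi-LSTM.
#' @param optimizer only `"rmsprop"` is supported.
#' @param learning_rate,epochs,batch_size training settings.
#' @param seed integer seed fixing initialization, batch order and dropout.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_size, n_classes, seq_len = 29L,
                         bilstm_units = 128L, dropout = 0.3,
                         lstm_units = 64L, dense_units = 128L,
                         optimizer = "rmsprop", learning_rate = 0.001,
                         epochs = 46L, batch_size = 32L, seed = 1L) {
  sizes <- c(input_size, n_classes, seq_len, bilstm_units, lstm_units,
             dense_units, epochs + 1L, batch_size)
  if (any(!is.finite(sizes)) || any(sizes < 1))
    stop_validation("all sizes must be positive (epochs >= 0)")
  if (n_classes < 2L) stop_validation("n_classes must be >= 2")
  if (dropout < 0 || dropout >= 1) stop_validation("dropout must be in [0, 1)")
  if (!identical(optimizer, "rmsprop"))
    stop_validation("only the rmsprop optimizer is supported")
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 seq_len = as.integer(seq_len),
                 bilstm_units = as.integer(bilstm_units),
                 dropout = dropout, lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "network_spec")
}

.glorot <- function(nr, nc, rng_fan = c(nc, nr)) {
  lim <- sqrt(6 / sum(rng_fan))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

.init_cell <- function(H, D) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(W = .glorot(4 * H, D, c(D, H)), U = .glorot(4 * H, H, c(H, H)), b = b)
}

#' Build an untrained network
#'
#' Initializes all parameters (Glorot-uniform weights, unit forget-gate
#' bias) deterministically from `spec$seed`.
#'
#' @param spec a [network_spec()].
#' @return An object of class `bilstm_model` with `spec`, `params`, and empty
#'   training state.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  H1 <- spec$bilstm_units; H2 <- spec$lstm_units
  f <- .init_cell(H1, spec$input_size)
  b <- .init_cell(H1, spec$input_size)
  l2 <- .init_cell(H2, 2L * H1)
  params <- list(W_f = f$W, U_f = f$U, b_f = f$b,
                 W_b = b$W, U_b = b$U, b_b = b$b,
                 W_2 = l2$W, U_2 = l2$U, b_2 = l2$b,
                 W_d1 = .glorot(spec$dense_units, H2), b_d1 = rep(0, spec$dense_units),
                 W_d2 = .glorot(spec$n_classes, spec$dense_units),
                 b_d2 = rep(0, spec$n_classes))
  structure(list(spec = spec, params = params, standardize = NULL,
                 classes = NULL, loss_history = numeric(0)),
            class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  s <- x$spec
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<bilstm_model> %d x %d input -> BiLSTM(%d) -> drop %.1f -> LSTM(%d) -> dense(%d) -> %d classes (%d params)%s\n",
    s$seq_len, s$input_size, s$bilstm_units, s$dropout, s$lstm_units,
    s$dense_units, s$n_classes, np,
    if (length(x$loss_history)) sprintf(", trained %d epochs", length(x$loss_history)) else ""))
  invisible(x)
}

.as_sequences <- function(sequences) {
  if (inherits(sequences, "feature_tensor")) sequences <- sequences$values
  if (length(dim(sequences)) != 3L)
    stop_validation("`sequences` must be a trials x windows x features array")
  sequences
}

#' Train the classifier
#'
#' Standardizes every feature by its training-set mean and SD (the statistics
#' are stored for inference), then runs `spec$epochs` epochs of RMSprop on
#' the cross-entropy loss. Fully deterministic given `spec$seed`.
#'
#' @param model a `bilstm_model` from [build_network()], or a
#'   [network_spec()] (a fresh network is built).
#' @param sequences trials x windows x features array or [feature_tensor()];
#'   must match `spec$seq_len` and `spec$input_size`.
#' @param labels per-trial labels; at least two classes must be present.
#' @return The trained `bilstm_model`, with `loss_history` (mean epoch loss).
#' @export
train_network <- function(model, sequences, labels) {
  if (inherits(model, "network_spec")) model <- build_network(model)
  stopifnot(inherits(model, "bilstm_model"))
  spec <- model$spec
  X <- .as_sequences(sequences)
  d <- dim(X)
  if (d[2L] != spec$seq_len || d[3L] != spec$input_size)
    stop_validation(sprintf("sequences are %d x %d but spec wants %d x %d",
                            d[2L], d[3L], spec$seq_len, spec$input_size))
  if (!all(is.finite(X))) stop_validation("non-finite values in sequences")
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop_validation("training labels contain a single class")
  if (length(classes) > spec$n_classes)
    stop_validation("more classes in labels than spec$n_classes")
  y <- match(labels, classes) - 1L
  mu <- apply(X, 3L, mean)
  sdv <- apply(X, 3L, sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- .standardize(X, mu, sdv)
  if (spec$epochs > 0L) {
    fit <- lstm_train_cpp(model$params, Xs, as.integer(y), spec$epochs,
                          spec$batch_size, spec$learning_rate, spec$dropout,
                          spec$seed)
    model$params <- fit$params
    model$loss_history <- c(model$loss_history, fit$loss_history)
  }
  model$standardize <- list(mean = mu, sd = sdv)
  model$classes <- classes
  model
}

.standardize <- function(X, mu, sdv) {
  d <- dim(X)
  Xs <- X
  for (j in seq_len(d[3L])) Xs[, , j] <- (X[, , j] - mu[j]) / sdv[j]
  Xs
}

#' Predict classes or probabilities
#'
#' @param object a trained `bilstm_model`.
#' @param newdata trials x windows x features array or [feature_tensor()].
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return Label vector or trials x classes probability matrix.
#' @export
predict.bilstm_model <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  X <- .as_sequences(newdata)
  if (!is.null(object$standardize))
    X <- .standardize(X, object$standardize$mean, object$standardize$sd)
  probs <- lstm_predict_cpp(object$params, X)
  classes <- object$classes %||% seq_len(object$spec$n_classes)
  probs <- probs[, seq_along(classes), drop = FALSE]
  colnames(probs) <- as.character(classes)
  if (type == "prob") return(probs)
  classes[max.col(probs, ties.method = "first")]
}
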