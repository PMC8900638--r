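# Evaluation protocols: leave-one-subject-out and stratified 10-fold CV.
# All fold-dependent fitting (feature standardization, optional MIPCA) is
# done inside the training fold only.

#' Feature sequences for a dataset bundle
#'
#' Runs the energy-sequence projection and windowed feature extraction on
#' every trial of a bundle and returns the stacked tensor.
#'
#' @param bundle a [dataset_bundle()].
#' @param weights `"uniform"`, or a [region_weighting()] (see
#'   [energy_sequence()]).
#' @param spec a [window_spec()].
#' @param inventory feature names (default full 49-entry inventory).
#' @param params a [feature_params()].
#' @return A [feature_tensor()] with one trial per bundle recording.
#' @export
bundle_features <- function(bundle, weights = "uniform",
                            spec = window_spec(),
                            inventory = default_inventory(),
                            params = feature_params()) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  tensors <- lapply(bundle$recordings, function(rec)
    extract_feature_set(energy_sequence(rec, weights), spec, inventory, params))
  stack_feature_tensors(tensors)
}

.fold_result <- function(spec, Xtr, ytr, Xte, yte, use_mipca, mipca_cutoff,
                         fold_seed) {
  if (use_mipca) {
    d <- dim(Xtr)
    flat <- matrix(Xtr, d[1L] * d[2L], d[3L])
    mod <- fit_mipca(flat, cutoff = mipca_cutoff)
    proj <- function(X) {
      dd <- dim(X)
      Z <- matrix(X, dd[1L] * dd[2L], dd[3L]) %*% t(mod$B_l)
      array(Z, c(dd[1L], dd[2L], mod$l))
    }
    Xtr <- proj(Xtr); Xte <- proj(Xte)
    spec <- do.call(network_spec, utils::modifyList(
      unclass(spec), list(input_size = mod$l)))
  }
  spec$seed <- fold_seed
  fit <- train_network(build_network(spec), Xtr, ytr)
  pred <- predict(fit, Xte)
  lev <- sort(unique(c(yte, pred, fit$classes)))
  cm <- table(factor(yte, lev), factor(pred, lev))
  list(accuracy = mean(pred == yte), confusion = cm,
       loss_history = fit$loss_history)
}

.make_report <- function(protocol, units, folds, spec) {
  acc <- vapply(folds, `[[`, 0, "accuracy")
  structure(list(protocol = protocol, units = units, accuracies = acc,
                 mean_accuracy = mean(acc),
                 confusion = lapply(folds, `[[`, "confusion"),
                 config = spec),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: mean accuracy %.4f over %d folds\n",
              x$protocol, x$mean_accuracy, length(x$accuracies)))
  for (i in seq_along(x$units))
    cat(sprintf("  %s: %.4f\n", x$units[i], x$accuracies[i]))
  invisible(x)
}

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: the network is trained on all other subjects'
#' trials and tested on the held-out subject. Feature standardization (and
#' MIPCA, when enabled) is fitted on the training folds only.
#'
#' @param bundle a [dataset_bundle()] (needs >= 2 subjects), or `NULL` when
#'   `features`, `labels` and `subjects` are given directly.
#' @param spec a [network_spec()].
#' @param features optional precomputed [feature_tensor()] or array aligned
#'   with the bundle trials (skips extraction).
#' @param labels,subjects per-trial vectors, required when `bundle` is NULL.
#' @param weights,window passed to [bundle_features()] when extraction runs.
#' @param subset named subset passed to [select_named_features()], or NULL
#'   for all columns.
#' @param use_mipca fit a MIPCA reduction inside each training fold and
#'   project both folds onto the retained components.
#' @param mipca_cutoff cumulative-contribution cutoff for that reduction.
#' @return An `evaluation_report` with per-subject accuracies and their mean.
#' @export
evaluate_loso <- function(bundle, spec, features = NULL, labels = NULL,
                          subjects = NULL, weights = "uniform",
                          window = window_spec(), subset = NULL,
                          use_mipca = FALSE, mipca_cutoff = 0.95) {
  prep <- .prep_eval(bundle, features, labels, subjects, weights, window,
                     subset)
  subj <- unique(prep$subjects)
  if (length(subj) < 2L) stop_validation("LOSO needs at least 2 subjects")
  folds <- lapply(seq_along(subj), function(i) {
    te <- prep$subjects == subj[i]
    if (length(unique(prep$labels[te])) < 2L)
      warning(sprintf("subject %s has a single class; still evaluated",
                      subj[i]))
    .fold_result(spec,
                 prep$X[!te, , , drop = FALSE], prep$labels[!te],
                 prep$X[te, , , drop = FALSE], prep$labels[te],
                 use_mipca, mipca_cutoff, fold_seed = spec$seed + i)
  })
  .make_report("loso", as.character(subj), folds, spec)
}

#' Stratified k-fold evaluation
#'
#' Trials are dealt into `k` label-stratified folds (deterministic under
#' `seed`); folds are disjoint and exhaustive.
#'
#' @inheritParams evaluate_loso
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed (defaults to `spec$seed`).
#' @return An `evaluation_report` with per-fold accuracies and their mean.
#' @export
evaluate_kfold <- function(bundle, spec, k = 10L, seed = NULL,
                           features = NULL, labels = NULL, subjects = NULL,
                           weights = "uniform", window = window_spec(),
                           subset = NULL, use_mipca = FALSE,
                           mipca_cutoff = 0.95) {
  prep <- .prep_eval(bundle, features, labels, subjects, weights, window,
                     subset)
  n <- length(prep$labels)
  if (k > n) stop_validation("k exceeds the number of trials")
  fold_of <- stratified_folds(prep$labels, k, seed %||% spec$seed)
  folds <- lapply(seq_len(k), function(i) {
    te <- fold_of == i
    .fold_result(spec,
                 prep$X[!te, , , drop = FALSE], prep$labels[!te],
                 prep$X[te, , , drop = FALSE], prep$labels[te],
                 use_mipca, mipca_cutoff, fold_seed = spec$seed + i)
  })
  .make_report("kfold10", sprintf("fold%02d", seq_len(k)), folds, spec)
}

#' Stratified fold assignment
#'
#' @param labels per-trial labels.
#' @param k number of folds.
#' @param seed RNG seed (deterministic assignment).
#' @return Integer vector in `1..k`, one entry per trial; class proportions
#'   are balanced across folds.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold_of <- integer(length(labels))
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx) %% k  # rotate remainder across classes
  }
  fold_of
}

.prep_eval <- function(bundle, features, labels, subjects, weights, window,
                       subset) {
  if (is.null(bundle)) {
    if (is.null(features) || is.null(labels))
      stop_validation("without a bundle, supply `features` and `labels`")
  } else {
    stopifnot(inherits(bundle, "dataset_bundle"))
    labels <- labels %||% bundle$labels
    subjects <- subjects %||% bundle$subjects
    if (is.null(features))
      features <- bundle_features(bundle, weights, window)
  }
  if (!is.null(subset) && inherits(features, "feature_tensor"))
    features <- select_named_features(features, subset)
  X <- .as_sequences(features)
  if (dim(X)[1L] != length(labels))
    stop_validation("features and labels disagree on the trial count")
  list(X = X, labels = labels,
       subjects = subjects %||% rep(1L, length(labels)))
}
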