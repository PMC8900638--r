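# RBF C-SVC baseline, trained by a simplified SMO. Small-n tool: kernel
# matrices are materialized. Implemented here because no SVM library is part
# of the supported dependency set.

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Simplified SMO on a precomputed kernel; y in {-1, 1}.
.smo_fit <- function(K, y, C, tol = 1e-3, max_passes = 8L, max_iter = 2e4L,
                     seed = 1L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L
  iter <- 0L
  rng <- seed
  nextr <- function() {  # small deterministic LCG, avoids touching R's RNG
    rng <<- (1103515245 * rng + 12345) %% 2147483648
    rng / 2147483648
  }
  fcache <- function(i) sum(alpha * y * K[, i]) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- fcache(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- floor(nextr() * (n - 1L)) + 1L
        if (j >= i) j <- j + 1L
        Ej <- fcache(j) - y[j]
        ai <- alpha[i]; aj <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj - ai); H <- min(C, C + aj - ai)
        } else {
          L <- max(0, ai + aj - C); H <- min(C, ai + aj)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj_new <- aj - y[j] * (Ei - Ej) / eta
        aj_new <- min(max(aj_new, L), H)
        if (abs(aj_new - aj) < 1e-5) next
        ai_new <- ai + y[i] * y[j] * (aj - aj_new)
        b1 <- b - Ei - y[i] * (ai_new - ai) * K[i, i] -
          y[j] * (aj_new - aj) * K[i, j]
        b2 <- b - Ej - y[i] * (ai_new - ai) * K[i, j] -
          y[j] * (aj_new - aj) * K[j, j]
        alpha[i] <- ai_new; alpha[j] <- aj_new
        b <- if (ai_new > 0 && ai_new < C) b1
             else if (aj_new > 0 && aj_new < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
      iter <- iter + 1L
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

.svm_train <- function(X, y, C, gamma, seed = 1L) {
  classes <- sort(unique(y))
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    ypm <- ifelse(y[sel] == pr[2L], 1, -1)
    Xs <- X[sel, , drop = FALSE]
    K <- .rbf_kernel(Xs, Xs, gamma)
    fit <- .smo_fit(K, ypm, C, seed = seed)
    list(pair = pr, X = Xs, y = ypm, alpha = fit$alpha, b = fit$b)
  })
  structure(list(models = models, classes = classes, gamma = gamma, C = C),
            class = "rbf_svm")
}

.svm_predict <- function(model, Xnew) {
  votes <- matrix(0L, nrow(Xnew), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (m in model$models) {
    K <- .rbf_kernel(Xnew, m$X, model$gamma)
    f <- as.numeric(K %*% (m$alpha * m$y)) + m$b
    win <- ifelse(f >= 0, m$pair[2L], m$pair[1L])
    votes[cbind(seq_len(nrow(Xnew)), match(win, model$classes))] <-
      votes[cbind(seq_len(nrow(Xnew)), match(win, model$classes))] + 1L
  }
  model$classes[max.col(votes, ties.method = "first")]
}

#' Penalty grid of the RBF C-SVC baseline
#'
#' @return `2^(-3:8)`, the 12-value grid scanned for the penalty C.
#' @export
svm_c_grid <- function() 2^(-3:8)

#' RBF C-SVC baseline on per-trial feature vectors
#'
#' The comparison path for the sequence classifier: each trial is summarized
#' by the window-wise mean of every feature, features are z-scored, and a
#' C-SVC with RBF kernel is evaluated by stratified cross-validation; inside
#' every training fold the penalty C is selected from [svm_c_grid()] by
#' 5-fold inner CV.
#'
#' @param features [feature_tensor()] (reduced to per-trial vectors by the
#'   window mean) or a trials x features matrix.
#' @param labels per-trial labels (>= 2 classes).
#' @param c_grid penalty grid (default [svm_c_grid()]).
#' @param outer_k,inner_k outer evaluation folds and inner selection folds.
#' @param seed fold-assignment seed.
#' @return List with `accuracy` (mean outer held-out accuracy),
#'   `fold_accuracies`, and `chosen_C` per outer fold.
#' @export
baseline_svm <- function(features, labels, c_grid = svm_c_grid(),
                         outer_k = 5L, inner_k = 5L, seed = 1L) {
  if (inherits(features, "feature_tensor"))
    X <- apply(features$values, c(1L, 3L), mean)
  else X <- as.matrix(features)
  if (length(unique(labels)) < 2L)
    stop_validation("need at least 2 classes")
  sdv <- apply(X, 2L, sd)
  if (all(sdv < 1e-12)) stop_validation("degenerate (constant) features")
  keep <- sdv > 1e-12
  X <- scale(X[, keep, drop = FALSE])
  gamma <- 1 / (ncol(X) * max(var(as.numeric(X)), 1e-12))
  outer_fold <- stratified_folds(labels, outer_k, seed)
  fold_acc <- numeric(outer_k)
  chosen <- numeric(outer_k)
  for (fo in seq_len(outer_k)) {
    tr <- outer_fold != fo
    Xtr <- X[tr, , drop = FALSE]; ytr <- labels[tr]
    inner_fold <- stratified_folds(ytr, inner_k, seed + fo)
    cv_acc <- vapply(c_grid, function(C) {
      accs <- vapply(seq_len(inner_k), function(fi) {
        itr <- inner_fold != fi
        m <- .svm_train(Xtr[itr, , drop = FALSE], ytr[itr], C, gamma,
                        seed = seed + fo)
        mean(.svm_predict(m, Xtr[!itr, , drop = FALSE]) == ytr[!itr])
      }, 0)
      mean(accs)
    }, 0)
    C_best <- c_grid[which.max(cv_acc)]
    chosen[fo] <- C_best
    m <- .svm_train(Xtr, ytr, C_best, gamma, seed = seed + fo)
    fold_acc[fo] <- mean(.svm_predict(m, X[!tr, , drop = FALSE]) == labels[!tr])
  }
  list(accuracy = mean(fold_acc), fold_accuracies = fold_acc,
       chosen_C = chosen)
}
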