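# Mutual-information + PCA reduction: a symmetric MI matrix across feature
# columns is eigendecomposed and components are kept up to a cumulative
# contribution cutoff. The printed procedure defines "probabilities" as value
# proportions, which is ill-posed for negative features and leaves the joint
# undefined; the estimator here is an equal-width histogram MI (bins =
# ceil(sqrt(m)) after min-shift), with the literal value-proportion entropy
# available for the diagonal via `literal = TRUE`.

#' Value proportions of feature columns
#'
#' Each column is shifted to be nonnegative (only when it contains negative
#' values, by adding `-min`) and normalized to sum to 1.
#'
#' @param X numeric matrix, samples in rows (m >= 2).
#' @return Matrix of the same shape with unit column sums. A column that is
#'   identically zero after the shift becomes uniform, with a flag attribute.
#' @export
value_proportions <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_validation("need at least 2 samples")
  flags <- character(0)
  P <- apply(X, 2L, function(col) {
    mn <- min(col)
    if (mn < 0) col <- col - mn
    s <- sum(col)
    if (s <= 0) {
      flags <<- c(flags, "zero_column:uniform_proportions")
      return(rep(1 / length(col), length(col)))
    }
    col / s
  })
  if (length(flags)) attr(P, "flags") <- flags
  P
}

#' Shannon entropy of a proportion column
#'
#' Natural log, with `0 * log(0) = 0`.
#'
#' @param p numeric vector of proportions summing to 1.
#' @return Scalar entropy in nats.
#' @export
feature_entropy <- function(p) {
  if (abs(sum(p) - 1) > 1e-8)
    stop_validation("proportions must sum to 1")
  .shannon(p)
}

# Equal-width bin index of a column; constant columns land in bin 1.
.bin_column <- function(col, bins) {
  rng <- range(col)
  if (rng[2L] - rng[1L] <= 0) return(rep(1L, length(col)))
  idx <- as.integer(floor((col - rng[1L]) / (rng[2L] - rng[1L]) * bins)) + 1L
  pmin(idx, bins)
}

#' Histogram mutual-information matrix
#'
#' Discretizes every feature column into `bins` equal-width bins and returns
#' the matrix of pairwise mutual informations (nats); the diagonal holds each
#' column's binned entropy, which equals `MI(X, X)`.
#'
#' The default bin count is the cube-root rule `ceiling(m^(1/3))`: the
#' histogram MI estimator has a positive bias of roughly
#' `(bins - 1)^2 / (2m)` nats for independent columns, so square-root-style
#' rules swamp the signal (0.5 nats at m = 1e4) while the cube-root rule
#' keeps the bias near 0.02 nats there.
#'
#' @param X numeric matrix, samples x features (needs `m >= 8 * bins`).
#' @param bins number of bins; default `ceiling(m^(1/3))`.
#' @return Symmetric `n x n` matrix.
#' @export
mutual_information_matrix <- function(X, bins = NULL) {
  X <- as.matrix(X)
  m <- nrow(X); n <- ncol(X)
  if (n < 2L) stop_validation("need at least 2 feature columns")
  bins <- as.integer(bins %||% max(4, ceiling(m^(1 / 3))))
  if (m < 8L * bins)
    stop_validation(sprintf(
      "MI estimation with %d bins needs at least %d samples (got %d)",
      bins, 8L * bins, m))
  B <- vapply(seq_len(n), function(j) .bin_column(X[, j], bins),
              integer(m))
  I <- matrix(0, n, n)
  marg <- lapply(seq_len(n), function(j) tabulate(B[, j], bins) / m)
  for (j in seq_len(n)) {
    I[j, j] <- .shannon(marg[[j]])
    for (k in seq_len(j - 1L)) {
      joint <- tabulate((B[, j] - 1L) * bins + B[, k], bins * bins) / m
      pj <- rep(marg[[j]], each = bins)
      pk <- rep(marg[[k]], times = bins)
      pos <- joint > 0
      I[j, k] <- I[k, j] <-
        sum(joint[pos] * log(joint[pos] / (pj[pos] * pk[pos])))
    }
  }
  dimnames(I) <- list(colnames(X), colnames(X))
  I
}

#' Fit a MIPCA reduction
#'
#' Computes the mutual-information matrix of the feature columns,
#' eigendecomposes it, and selects the smallest number of leading components
#' whose cumulative contribution rate reaches `cutoff`.
#'
#' @param X numeric matrix, samples x features.
#' @param cutoff cumulative contribution cutoff in (0, 1]; conventionally
#'   0.85-0.95, default 0.95.
#' @param bins histogram bins (default `ceiling(sqrt(m))`).
#' @param literal replace the MI diagonal with the literal value-proportion
#'   entropies of Steps 1-2 of the printed procedure.
#' @return A `mipca_model` with `mi_matrix`, `eigenvalues`, `B` (eigenvector
#'   rows, sign-fixed so each row's largest-magnitude entry is positive),
#'   `contrib`, `cum_contrib`, `l`, `B_l`, `cutoff`.
#' @seealso [mipca_from_mi()] for fitting from a precomputed matrix,
#'   [predict.mipca_model()] for the projection.
#' @export
fit_mipca <- function(X, cutoff = 0.95, bins = NULL, literal = FALSE) {
  M <- mutual_information_matrix(X, bins)
  if (literal) {
    P <- value_proportions(X)
    diag(M) <- apply(P, 2L, feature_entropy)
  }
  mipca_from_mi(M, cutoff)
}

#' @rdname fit_mipca
#' @param M precomputed symmetric nonnegative matrix (an MI matrix).
#' @export
mipca_from_mi <- function(M, cutoff = 0.95) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff > 1)
    stop_validation("cutoff must lie in (0, 1]")
  if (!all(is.finite(M)))
    stop_dynergy("MI matrix contains non-finite values", "dynergy_numeric_error")
  if (max(abs(M - t(M))) > 1e-10)
    stop_validation("MI matrix must be symmetric")
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  B <- t(eig$vectors)  # rows are eigenvectors beta_k, descending eigenvalue
  for (k in seq_len(nrow(B))) {
    j <- which.max(abs(B[k, ]))
    if (B[k, j] < 0) B[k, ] <- -B[k, ]
  }
  mu <- eig$values
  contrib <- mu / sum(mu)
  cum <- cumsum(contrib)
  l <- which(cum >= cutoff - 1e-12)[1L]
  if (is.na(l)) l <- length(mu)
  structure(list(mi_matrix = M, eigenvalues = mu, B = B,
                 contrib = contrib, cum_contrib = cum,
                 l = l, B_l = B[seq_len(l), , drop = FALSE],
                 cutoff = cutoff),
            class = "mipca_model")
}

#' @export
print.mipca_model <- function(x, ...) {
  cat(sprintf("<mipca_model> %d features -> %d components (cutoff %.2f)\n",
              ncol(x$B), x$l, x$cutoff))
  cat(sprintf("  cumulative contribution at l: %.4f\n", x$cum_contrib[x$l]))
  invisible(x)
}

#' Project samples onto the retained components
#'
#' `Z = X B_l'` in the samples-by-features orientation: row `i` of the result
#' holds the coordinates of sample `i` on the `l` retained eigenvectors.
#'
#' @param object a `mipca_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return `m x l` numeric matrix.
#' @export
predict.mipca_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$B))
    stop_validation(sprintf("model expects %d feature columns, got %d",
                            ncol(object$B), ncol(newdata)))
  newdata %*% t(object$B_l)
}

#' Serialize / load a MIPCA model (HDF5)
#'
#' @param model a `mipca_model`.
#' @param path HDF5 file path.
#' @return `path` (write) or the model (read).
#' @export
write_mipca <- function(model, path) {
  stopifnot(inherits(model, "mipca_model"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(model$mi_matrix, path, "mi_matrix")
  rhdf5::h5write(model$eigenvalues, path, "eigenvalues")
  rhdf5::h5write(model$B, path, "B")
  rhdf5::h5write(model$cutoff, path, "cutoff")
  invisible(path)
}

#' @rdname write_mipca
#' @export
read_mipca <- function(path) {
  M <- rhdf5::h5read(path, "mi_matrix")
  cutoff <- as.numeric(rhdf5::h5read(path, "cutoff"))
  mipca_from_mi(M, cutoff)
}
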