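# Time-domain descriptors of one window of the energy sequence. All
# dispersion statistics use the population (1/N) form, matching the printed
# definitions.

.popvar <- function(x) mean((x - mean(x))^2)
.popsd <- function(x) sqrt(.popvar(x))

#' Time-domain feature set of a window
#'
#' Nine statistics: mean, population SD, mean absolute first and second
#' differences (raw and SD-normalized), instability index (NSI), signal
#' energy, and Higuchi fractal dimension.
#'
#' @param x numeric window (length >= 3; >= `nsi_segments` for the NSI).
#' @param nsi_segments number of equal-length segments for the NSI
#'   (default 20).
#' @param fd_kmax largest interval scale for the Higuchi estimator
#'   (default 8).
#' @return Named numeric vector
#'   `c(mean, sd, diff1, diff1_norm, diff2, diff2_norm, nsi, energy, fd)`.
#'   When the window is constant, the normalized differences are 0 and the
#'   fractal dimension is 1, with a `"flags"` attribute recording it.
#' @export
time_domain_features <- function(x, nsi_segments = 20L, fd_kmax = 8L) {
  n <- length(x)
  if (n < 3L) stop_validation("window must have at least 3 samples")
  flags <- character(0)
  mu <- mean(x)
  sdv <- .popsd(x)
  d1 <- mean(abs(diff(x)))
  d2 <- sum(abs(x[3:n] - x[1:(n - 2L)])) / (n - 2L)
  if (sdv > 0) {
    d1n <- d1 / sdv; d2n <- d2 / sdv
  } else {
    d1n <- 0; d2n <- 0
    flags <- c(flags, "zero_sd:diff_norm_set_to_0")
  }
  nv <- nsi(x, nsi_segments)
  flags <- c(flags, attr(nv, "flags"))
  out <- c(mean = mu, sd = sdv, diff1 = d1, diff1_norm = d1n,
           diff2 = d2, diff2_norm = d2n,
           nsi = as.numeric(nv),
           energy = sum(x^2),
           fd = NA_real_)
  fd <- higuchi_fd(x, fd_kmax)
  if (is.na(fd)) {
    fd <- 1.0
    flags <- c(flags, "constant_window:fd_set_to_1")
  }
  out["fd"] <- fd
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Instability index
#'
#' Splits the window into `m` equal-length segments (any remainder samples
#' are dropped) and returns the population SD of the segment means.
#'
#' @param x numeric window.
#' @param m number of segments (default 20); when the window is shorter than
#'   `m`, every sample becomes its own segment (flagged).
#' @return Scalar NSI.
#' @export
nsi <- function(x, m = 20L) {
  n <- length(x)
  flag <- NULL
  if (n < m) {
    m <- n
    flag <- "short_window:nsi_segments_reduced"
  }
  seg <- n %/% m
  means <- colMeans(matrix(x[seq_len(seg * m)], nrow = seg))
  out <- .popsd(means)
  if (!is.null(flag)) attr(out, "flags") <- flag
  out
}

#' Higuchi fractal dimension
#'
#' Average normalized curve length `L(k)` over start offsets `m = 1..k` for
#' interval scales `k = 1..k_max`; the dimension is the negated least-squares
#' slope of `log L(k)` on `log k`, which is exactly 1 for a straight line.
#'
#' @param x numeric window.
#' @param k_max largest scale (default 8); requires `length(x) > 2 * k_max`.
#' @return Scalar dimension, or `NA` for a constant window (zero curve
#'   length).
#' @export
higuchi_fd <- function(x, k_max = 8L) {
  n <- length(x)
  k_max <- min(k_max, n %/% 2L)  # every offset needs >= 1 interval
  if (k_max < 2L)
    stop_validation("Higuchi FD needs at least 4 samples")
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      sub <- x[seq.int(m, n, by = k)]
      nk <- length(sub) - 1L
      (n - 1) / (nk * k^2) * sum(abs(diff(sub)))
    }, 0)
    mean(lm_k)
  }, 0)
  if (any(lk <= 0)) return(NA_real_)
  logk <- log(seq_len(k_max))
  -as.numeric(stats::coef(stats::lm.fit(cbind(1, logk), log(lk)))[2L])
}
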