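# Dynamical (non-linear) descriptors: approximate entropy, wavelet entropy
# of a six-level db4 decomposition, and band differential entropy.

#' Approximate entropy
#'
#' `ApEn = Phi_m(r) - Phi_{m+1}(r)` with template vectors compared under the
#' Chebyshev (maximum) distance, strict tolerance `d < r`, and self-matches
#' included, so both correlation sums are strictly positive.
#'
#' @param x numeric window (length >= m + 2).
#' @param m embedding dimension (default 2).
#' @param r similarity tolerance; default `0.2 * sd(x)` (population SD).
#' @return Scalar entropy (>= 0 up to floating error; 0 for a constant
#'   window).
#' @export
approximate_entropy <- function(x, m = 2L, r = NULL) {
  n <- length(x)
  if (is.null(r)) r <- 0.2 * .popsd(x)
  if (!is.numeric(r) || length(r) != 1L || r < 0)
    stop_dynergy("`r` must be a nonnegative scalar", "dynergy_parameter_error")
  if (r == 0) r <- .Machine$double.eps  # constant window: everything matches
  if (n < m + 2L)
    stop_validation(sprintf("ApEn needs length >= %d", m + 2L))
  apen_cpp(as.numeric(x), as.integer(m), as.numeric(r))
}

# db4 (Daubechies extremal-phase, 4 vanishing moments) scaling filter.
.db4_h <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997)
.db4_g <- rev(.db4_h) * c(1, -1)  # (-1)^k h[L-1-k], k = 0..7

# One periodized analysis step: x (even length) -> list(a, d), each n/2.
.dwt_step <- function(x) {
  n <- length(x)
  idx <- outer(seq(0L, n - 2L, by = 2L), 0:7, `+`) %% n + 1L
  xm <- matrix(x[idx], ncol = 8L)
  list(a = as.numeric(xm %*% .db4_h), d = as.numeric(xm %*% .db4_g))
}

#' Six-level db4 wavelet decomposition
#'
#' Periodized pyramid transform; odd-length intermediates are padded by
#' repeating the last sample (recorded in the `"flags"` attribute).
#'
#' @param x numeric window.
#' @param levels decomposition depth (default 6).
#' @return Named list of coefficient vectors `d1..d<levels>`, `a<levels>`.
#' @export
wavelet_decompose <- function(x, levels = 6L) {
  out <- list()
  flags <- character(0)
  a <- as.numeric(x)
  for (lev in seq_len(levels)) {
    if (length(a) %% 2L == 1L) {
      a <- c(a, a[length(a)])
      flags <- c(flags, sprintf("odd_length_padded:level%d", lev))
    }
    if (length(a) < 2L) stop_validation("window too short for the decomposition")
    s <- .dwt_step(a)
    out[[paste0("d", lev)]] <- s$d
    a <- s$a
  }
  out[[paste0("a", levels)]] <- a
  if (length(flags)) attr(out, "flags") <- flags
  out
}

.shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Wavelet entropy features
#'
#' Decomposes the window with a six-level db4 transform and reports, for the
#' approximation component A6 and each detail component D1..D6, the Shannon
#' entropy (natural log) of the normalized squared-coefficient distribution
#' within the component, plus the total wavelet entropy of the 7 relative
#' component energies.
#'
#' @param x numeric window.
#' @return Named vector `we_a6, we_d1..we_d6, we_total` (an all-zero
#'   component has entropy 0; a single-component signal has total entropy 0).
#' @export
wavelet_entropy <- function(x) {
  dec <- wavelet_decompose(x, 6L)
  comps <- dec[c("a6", paste0("d", 1:6))]
  out <- wavelet_entropy_from_coeffs(comps)
  names(out) <- c("we_a6", paste0("we_d", 1:6), "we_total")
  fl <- attr(dec, "flags")
  if (length(fl)) attr(out, "flags") <- fl
  out
}

#' @rdname wavelet_entropy
#' @param coeffs named list of 7 component coefficient vectors (approximation
#'   first), as from [wavelet_decompose()].
#' @export
wavelet_entropy_from_coeffs <- function(coeffs) {
  ent <- vapply(coeffs, function(cf) {
    e <- cf^2
    tot <- sum(e)
    if (tot <= 0) return(0)
    .shannon(e / tot)
  }, 0)
  energies <- vapply(coeffs, function(cf) sum(cf^2), 0)
  tot <- sum(energies)
  we_total <- if (tot > 0) .shannon(energies / tot) else 0
  c(ent, total = we_total)
}

#' Differential entropy of a band-limited window
#'
#' `DE = 0.5 * ln(2 * pi * e * var)` with the population variance of the
#' DFT-band-limited signal; equals 0 when the band variance is `1/(2*pi*e)`.
#'
#' @param x numeric window.
#' @param b a [band()] or band name (`"all"` uses the raw window).
#' @param fs sampling rate in Hz.
#' @return Scalar entropy in nats; a zero-variance band returns the large
#'   negative sentinel `0.5*ln(2*pi*e*1e-300)` with a flag attribute.
#' @export
differential_entropy <- function(x, b, fs) {
  y <- bandpass_dft(x, b, fs)
  v <- .popvar(y)
  # DFT masking of an out-of-band signal leaves O(1e-16) roundoff residue;
  # treat anything below 1e-24 as numerically zero variance
  if (v < 1e-24) {
    out <- 0.5 * log(2 * pi * exp(1) * 1e-300)
    attr(out, "flags") <- "zero_variance_band:de_sentinel"
    return(out)
  }
  0.5 * log(2 * pi * exp(1) * v)
}
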