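# Frequency-domain descriptors: Hjorth parameters of the DFT-band-limited
# signal, and AR (Burg) power-spectrum summaries per band.

#' Hjorth parameters of a band-limited window
#'
#' The window is band-limited by DFT masking ([bandpass_dft()]); activity is
#' the population variance of the band signal, mobility the RMS ratio of its
#' derivative (first difference scaled by `fs`) to the signal, and
#' complexity the mobility ratio of derivative to signal.
#'
#' With `mode = "spectral"` the same three ratios are computed on the complex
#' DFT coefficient sequence of the band instead of the time-domain samples,
#' for fidelity comparisons with the transform-then-Hjorth reading.
#'
#' @param x numeric window.
#' @param b a [band()] or band name.
#' @param fs sampling rate in Hz.
#' @param mode `"time"` (default) or `"spectral"`.
#' @return `c(activity, mobility, complexity)`; `(0, 0, 0)` with a flag
#'   attribute when the band signal has zero variance.
#' @export
hjorth_band <- function(x, b, fs, mode = c("time", "spectral")) {
  mode <- match.arg(mode)
  y <- bandpass_dft(x, b, fs)
  if (mode == "spectral") {
    n <- length(x)
    if (is.character(b)) b <- band(b, fs = fs)
    f <- (seq_len(n) - 1L) * fs / n
    keep <- pmin(f, fs - f) >= b$lo & pmin(f, fs - f) <= b$hi
    y <- fft(x)[keep]
  }
  .hjorth(y, fs)
}

.cvar <- function(z) mean(Mod(z - mean(z))^2)

.hjorth <- function(y, fs) {
  v0 <- .cvar(y)
  if (v0 < .Machine$double.eps) {
    out <- c(activity = 0, mobility = 0, complexity = 0)
    attr(out, "flags") <- "zero_variance_band:hjorth_set_to_0"
    return(out)
  }
  d1 <- diff(y) * fs
  d2 <- diff(d1) * fs
  v1 <- .cvar(d1); v2 <- .cvar(d2)
  mo <- sqrt(v1 / v0)
  co <- if (v1 > 0) sqrt(v2 / v1) / mo else 0
  c(activity = Re(v0), mobility = mo, complexity = co)
}

#' AR power-spectrum features per band
#'
#' Fits an autoregressive model of order `p` by Burg's method and evaluates
#' the AR power spectrum `P(w) = s2 / |1 - sum_k a_k exp(-i w k)|^2` on a
#' uniform grid over `[0, fs/2]`. For each requested band it reports the
#' frequency of the spectral maximum and the sum of spectral values over the
#' in-band grid points.
#'
#' @param x numeric window (length > `2 * p`).
#' @param fs sampling rate in Hz.
#' @param p AR order (default 10).
#' @param bands character vector of band names (default the five Hjorth
#'   bands).
#' @param n_grid grid size (default 512).
#' @return Named vector with `sp_maxfreq_<band>` and `sp_powsum_<band>`
#'   entries. Falls back to the periodogram (with a flag) if the AR fit is
#'   unusable.
#' @export
ar_spectrum_features <- function(x, fs, p = 10L,
                                 bands = .band_names_hjorth, n_grid = 512L) {
  n <- length(x)
  if (n <= 2L * p)
    stop_validation(sprintf("AR fit of order %d needs length > %d", p, 2L * p))
  freq <- seq(0, fs / 2, length.out = n_grid)
  spec <- NULL
  flags <- character(0)
  fit <- tryCatch(stats::ar(x, aic = FALSE, order.max = p, method = "burg"),
                  error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$var.pred) && fit$var.pred > 0 &&
      all(is.finite(fit$ar)) && all(Mod(polyroot(c(1, -fit$ar))) > 1)) {
    w <- 2 * pi * freq / fs
    ew <- exp(-1i * outer(w, seq_len(fit$order)))
    denom <- Mod(1 - as.vector(ew %*% fit$ar))^2
    spec <- fit$var.pred / denom
  } else {
    flags <- "unstable_ar_fit:periodogram_fallback"
    xf <- Mod(fft(x - mean(x)))^2 / n
    fbin <- (seq_len(n) - 1L) * fs / n
    half <- fbin <= fs / 2
    spec <- stats::approx(fbin[half], xf[half], xout = freq, rule = 2)$y
  }
  out <- numeric(0)
  for (bn in bands) {
    b <- band(bn, fs = fs)
    inb <- freq >= b$lo & freq <= b$hi
    sub <- spec[inb]
    out[paste0("sp_maxfreq_", bn)] <- freq[inb][which.max(sub)]
    out[paste0("sp_powsum_", bn)] <- sum(sub)
  }
  if (length(flags)) attr(out, "flags") <- flags
  out
}
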