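# Frequency bands. Method-section edges: theta 4-7, alpha 8-13, beta 14-30,
# gamma 31-50 Hz; "all" is the full band (0..fs/2, i.e. no masking). Delta
# (1-4 Hz) is defined because differential entropy is computed there too.

#' Frequency band
#'
#' @param name band name; one of `delta`, `theta`, `alpha`, `beta`, `gamma`,
#'   `all`, or a custom label when `lo`/`hi` are given.
#' @param lo,hi band edges in Hz; defaults come from the named presets
#'   (delta 1-4, theta 4-7, alpha 8-13, beta 14-30, gamma 31-50; `all` spans
#'   0 to `fs/2`).
#' @param fs sampling rate, needed to resolve `all` and to validate edges
#'   against Nyquist.
#' @return A list with `name`, `lo`, `hi` of class `band`.
#' @export
band <- function(name, lo = NULL, hi = NULL, fs = NULL) {
  presets <- list(delta = c(1, 4), theta = c(4, 7), alpha = c(8, 13),
                  beta = c(14, 30), gamma = c(31, 50))
  if (is.null(lo) || is.null(hi)) {
    if (name == "all") {
      if (is.null(fs)) stop_validation("band 'all' needs `fs`")
      lo <- 0; hi <- fs / 2
    } else if (name %in% names(presets)) {
      lo <- presets[[name]][1L]; hi <- presets[[name]][2L]
    } else stop_validation(sprintf("unknown band '%s' without edges", name))
  }
  if (!(lo >= 0 && lo < hi)) stop_validation("need 0 <= lo < hi")
  if (!is.null(fs) && hi > fs / 2 + 1e-9)
    stop_validation(sprintf("band [%g, %g] exceeds Nyquist (%g Hz)",
                            lo, hi, fs / 2))
  structure(list(name = name, lo = lo, hi = hi), class = "band")
}

.band_names_hjorth <- c("theta", "alpha", "beta", "gamma", "all")
.band_names_de <- c("delta", "theta", "alpha", "beta", "gamma", "all")

#' Band-limit a signal by DFT masking
#'
#' Forward DFT, zeroing of all bins whose frequency falls outside
#' `[lo, hi]` (both half-axes), inverse DFT. The `all` band keeps every bin
#' and returns the input unchanged.
#'
#' @param x numeric vector.
#' @param b a [band()] (or band name resolved at `fs`).
#' @param fs sampling rate in Hz.
#' @return Real numeric vector of the same length.
#' @export
bandpass_dft <- function(x, b, fs) {
  if (is.character(b)) b <- band(b, fs = fs)
  n <- length(x)
  if (b$lo <= 0 && b$hi >= fs / 2) return(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency of each bin
  keep <- f >= b$lo & f <= b$hi
  X <- fft(x)
  X[!keep] <- 0
  Re(fft(X, inverse = TRUE)) / n
}
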