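#' Per-channel weights from a region weighting
#'
#' Splits each region's coefficient mass equally across the channels of that
#' region, so that the weights sum to 1 and the unweighted cross-channel mean
#' is recovered when a single region carries all the mass.
#'
#' @param weighting a [region_weighting()], or `NULL` for uniform `1/N`.
#' @param channel_names channels of the recording, in row order.
#' @return Numeric weight vector named by channel, summing to 1.
#' @examples
#' w <- channel_weights(load_region_weighting(dataset = "seed"),
#'                      names(load_region_weighting(dataset = "seed")$region_of_channel))
#' sum(w)
#' @export
channel_weights <- function(weighting, channel_names) {
  n <- length(channel_names)
  if (is.null(weighting))
    return(stats::setNames(rep(1 / n, n), channel_names))
  stopifnot(inherits(weighting, "region_weighting"))
  key <- .norm_channel(channel_names)
  reg <- weighting$region_of_channel[key]
  if (anyNA(reg))
    stop_validation(sprintf("channel '%s' has no region assignment",
                            channel_names[which(is.na(reg))[1L]]))
  counts <- table(factor(reg, levels = names(weighting$region_sum)))
  used <- names(counts)[counts > 0]
  if (any(weighting$region_sum[used] > 0 & counts[used] == 0))
    stop_validation("a region with positive mass has no channels")  # nocov
  w <- weighting$region_sum[as.character(reg)] / as.numeric(counts[as.character(reg)])
  # renormalize in case some region of the montage is absent from the data
  if (abs(sum(w) - 1) > 1e-12) {
    present_mass <- sum(weighting$region_sum[used])
    if (present_mass <= 0) stop_validation("no region mass over these channels")
    w <- w / present_mass
  }
  stats::setNames(as.numeric(w), channel_names)
}

#' Energy sequence of a recording
#'
#' Projects an N-channel signal onto a single equal-length series by a
#' weighted cross-channel average at each sample:
#' `ET(t) = sum_i w_i * s(t, i)`. With uniform weights this is the plain
#' channel mean, whose added-noise variance is `1/N` of a single channel's;
#' regional weights emphasise scalp areas with stronger emotional activation.
#'
#' @param rec an [eeg_recording()].
#' @param weights `"uniform"`, a [region_weighting()], or a numeric vector of
#'   per-channel weights (recycled checks apply; length must equal the
#'   channel count).
#' @return An object of class `energy_sequence` with `values`, `fs`,
#'   `weighting`.
#' @examples
#' rec <- eeg_recording(rbind(c(1, 3), c(3, 1)), fs = 1)
#' energy_sequence(rec)$values  # c(2, 2)
#' @export
energy_sequence <- function(rec, weights = "uniform") {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- n_channels(rec)
  if (inherits(weights, "region_weighting")) {
    w <- channel_weights(weights, rec$channel_names)
    kind <- "regional"
  } else if (identical(weights, "uniform")) {
    w <- rep(1 / n, n)
    kind <- "uniform"
  } else {
    if (!is.numeric(weights) || length(weights) != n)
      stop_validation(sprintf(
        "`weights` must have one entry per channel (%d)", n))
    w <- as.numeric(weights)
    kind <- "custom"
  }
  if (anyNA(rec$data)) stop_validation("NaN in recording data")
  vals <- as.numeric(crossprod(rec$data, w))  # t(data) %*% w, length T
  structure(list(values = vals, fs = rec$fs, weighting = kind),
            class = "energy_sequence")
}

#' @export
print.energy_sequence <- function(x, ...) {
  cat(sprintf("<energy_sequence> %d samples @ %g Hz, %s weighting\n",
              length(x$values), x$fs, x$weighting))
  invisible(x)
}

#' Moving-window specification
#'
#' @param width_s window width in seconds (default 4).
#' @param step_s move step in seconds (default 2); must satisfy
#'   `0 < step_s <= width_s`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width_s = 4, step_s = 2) {
  if (!is.numeric(width_s) || width_s <= 0)
    stop_validation("width_s must be positive")
  if (!is.numeric(step_s) || step_s <= 0 || step_s > width_s)
    stop_validation("step_s must satisfy 0 < step_s <= width_s")
  structure(list(width_s = width_s, step_s = step_s), class = "window_spec")
}

#' Slice an energy sequence into overlapping windows
#'
#' Windows are half-open sample intervals `[start, start + width)` starting
#' at samples `0, step, 2*step, ...` (in samples); a trailing partial window
#' is dropped. A 60-s trial with 4-s windows and a 2-s step yields 29 windows
#' of 800 samples at 200 Hz (512 at 128 Hz).
#'
#' @param es an [energy_sequence()], or a plain numeric vector together with
#'   `fs`.
#' @param spec a [window_spec()].
#' @param fs sampling rate, only when `es` is a bare vector.
#' @return List of numeric windows, each of length `width_s * fs`.
#' @export
slide_windows <- function(es, spec = window_spec(), fs = NULL) {
  if (inherits(es, "energy_sequence")) {
    x <- es$values; fs <- es$fs
  } else {
    if (is.null(fs)) stop_validation("supply `fs` for a bare numeric series")
    x <- as.numeric(es)
  }
  stopifnot(inherits(spec, "window_spec"))
  w <- round(spec$width_s * fs)
  step <- round(spec$step_s * fs)
  n <- length(x)
  if (n < w)
    stop_validation(sprintf(
      "signal (%d samples) shorter than one window (%d samples)", n, w))
  starts <- seq.int(0L, n - w, by = step)
  lapply(starts, function(s) x[(s + 1L):(s + w)])
}
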