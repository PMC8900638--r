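#' Multichannel EEG recording
#'
#' Container for one trial of multichannel EEG: a channels-by-samples numeric
#' matrix together with its sampling rate and ordered channel names. Values
#' are conventionally microvolts but units are not enforced.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector, one name per row of `data`. Defaults
#'   to `ch1, ch2, ...`.
#' @param trial_id,subject_id,label optional scalar metadata.
#'
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_names`, `trial_id`, `subject_id`, `label`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(8), 2), fs = 4)
#' n_channels(rec)
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          trial_id = NULL, subject_id = NULL, label = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_validation("`data` must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_validation("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop_validation(sprintf(
      "`data` has %d rows but %d channel names were given",
      nrow(data), length(channel_names)))
  if (anyDuplicated(channel_names))
    stop_validation("channel names must be unique")
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop_validation(sprintf(
      "non-finite values in channel '%s' (and possibly others)",
      channel_names[bad[1L]]))
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = as.numeric(fs), channel_names = channel_names,
         trial_id = trial_id, subject_id = subject_id, label = label),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$subject_id) || !is.null(x$label))
    cat(sprintf("  subject: %s  trial: %s  label: %s\n",
                x$subject_id %||% "?", x$trial_id %||% "?", x$label %||% "?"))
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Dataset bundle
#'
#' A list of recordings with aligned per-trial labels and subject ids, as
#' consumed by the evaluation protocols.
#'
#' @param recordings list of [eeg_recording()] objects.
#' @param labels per-trial class labels (integer or factor-coercible).
#' @param subjects per-trial subject identifiers.
#' @param label_scheme one of `"seed2"`, `"seed3"`, `"deap_valence"`,
#'   `"deap_arousal"`, or `"custom"`.
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(recordings, labels, subjects,
                           label_scheme = c("custom", "seed2", "seed3",
                                            "deap_valence", "deap_arousal")) {
  label_scheme <- match.arg(label_scheme)
  if (!is.list(recordings) ||
      !all(vapply(recordings, inherits, TRUE, "eeg_recording")))
    stop_validation("`recordings` must be a list of eeg_recording objects")
  n <- length(recordings)
  if (length(labels) != n || length(subjects) != n)
    stop_validation("`labels` and `subjects` must match length(recordings)")
  n_class <- c(seed2 = 2L, seed3 = 3L, deap_valence = 2L, deap_arousal = 2L)
  labels <- as.integer(labels)
  if (label_scheme != "custom" &&
      !all(labels %in% seq_len(n_class[[label_scheme]])))
    stop_validation(sprintf("labels outside the %s class set", label_scheme))
  structure(list(recordings = recordings, labels = labels,
                 subjects = subjects, label_scheme = label_scheme),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %d trials, %d subjects, scheme '%s'\n",
              length(x$recordings), length(unique(x$subjects)),
              x$label_scheme))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 as.integer(table(x$labels))),
                         collapse = " "), "\n")
  invisible(x)
}
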