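# Synthetic EEG generator. Each trial is a sum of band-limited oscillatory
# components shared across channels (scaled by a per-region gain and a
# per-subject channel gain), plus iid Gaussian channel noise and a
# per-subject DC offset. Class identity acts only through the per-band
# component amplitudes, so the generator's ground truth is recoverable from
# band features of the energy sequence.

#' Synthetic dataset configuration
#'
#' Defaults state the reference world of the end-to-end checks: a
#' 62-channel, 200 Hz, 60-s (SEED-like) corpus of 5 subjects x 40 trials,
#' two classes whose gamma-band component amplitude differs by a factor 2
#' (all other bands equal), unit channel noise, and mild subject effects.
#'
#' @param n_subjects,trials_per_subject corpus shape (default 5 x 40).
#' @param n_channels 62 (SEED-like) or 32 (DEAP-like) pick the preset
#'   montage; other values get generic channel names and uniform regions.
#' @param fs sampling rate, Hz (200 SEED-like, 128 DEAP-like).
#' @param duration_s trial length in seconds (default 60).
#' @param class_band_power list with one named amplitude vector per class
#'   over bands `delta, theta, alpha, beta, gamma`.
#' @param channel_noise_sd SD of the iid per-channel noise (default 1).
#' @param subject_effect_sd SD of the per-subject channel gains (around 1)
#'   and DC offsets (default 0.1).
#' @param seed integer fixing the whole data stream.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 5L, trials_per_subject = 40L,
                             n_channels = 62L, fs = 200, duration_s = 60,
                             class_band_power = default_class_band_power(),
                             channel_noise_sd = 1, subject_effect_sd = 0.1,
                             seed = 1L) {
  counts <- c(n_subjects, trials_per_subject, n_channels, fs, duration_s)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop_validation("all counts must be positive")
  if (!is.list(class_band_power) || length(class_band_power) < 2L)
    stop_validation("class_band_power needs at least 2 classes")
  if (any(unlist(class_band_power) < 0))
    stop_validation("band amplitudes must be nonnegative")
  if (channel_noise_sd < 0 || subject_effect_sd < 0)
    stop_validation("noise SDs must be nonnegative")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s,
                 class_band_power = class_band_power,
                 channel_noise_sd = channel_noise_sd,
                 subject_effect_sd = subject_effect_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_class_band_power <- function() {
  base <- c(delta = 1, theta = 1, alpha = 1, beta = 1, gamma = 1)
  list(`1` = base, `2` = replace(base, "gamma", 2))
}

.derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.montage_for <- function(cfg) {
  if (cfg$n_channels == 62L || cfg$n_channels == 32L) {
    w <- load_region_weighting(dataset = if (cfg$n_channels == 62L) "seed" else "deap")
    ch <- names(w$region_of_channel)
    gain <- as.numeric(w$region_sum[as.character(w$region_of_channel)]) *
      length(w$region_sum)  # mean 1 across regions
    list(channels = ch, region_gain = gain)
  } else {
    list(channels = paste0("ch", seq_len(cfg$n_channels)),
         region_gain = rep(1, cfg$n_channels))
  }
}

.subject_effects <- function(cfg, subject_id) {
  .with_seed(.derive_seed(cfg$seed, 7919, subject_id), {
    list(gain = 1 + rnorm(cfg$n_channels) * cfg$subject_effect_sd,
         offset = rnorm(cfg$n_channels) * cfg$subject_effect_sd)
  })
}

#' Generate one synthetic trial
#'
#' @param cfg a [synthetic_config()].
#' @param class_id class in `1..length(cfg$class_band_power)`.
#' @param subject_id subject index (fixes the subject's channel gains).
#' @param trial_index trial index within the subject (fixes the noise
#'   stream).
#' @return An [eeg_recording()] of shape `n_channels x (fs * duration_s)`.
#' @export
generate_trial <- function(cfg, class_id, subject_id, trial_index = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.numeric(class_id) || length(class_id) != 1L ||
      class_id < 1 || class_id > length(cfg$class_band_power))
    stop_validation(sprintf("class %s not in the configuration", class_id))
  amps <- cfg$class_band_power[[class_id]]
  nt <- round(cfg$fs * cfg$duration_s)
  mon <- .montage_for(cfg)
  sub <- .subject_effects(cfg, subject_id)
  data <- .with_seed(.derive_seed(cfg$seed, subject_id, trial_index, class_id), {
    common <- numeric(nt)
    for (bn in names(amps)) {
      if (amps[[bn]] <= 0) next
      z <- bandpass_dft(rnorm(nt), band(bn, fs = cfg$fs), cfg$fs)
      s <- .popsd(z)
      if (s > 0) common <- common + amps[[bn]] * z / s
    }
    gains <- mon$region_gain * sub$gain
    outer(gains, common) + sub$offset +
      matrix(rnorm(cfg$n_channels * nt) * cfg$channel_noise_sd,
             cfg$n_channels, nt)
  })
  eeg_recording(data, fs = cfg$fs, channel_names = mon$channels,
                trial_id = trial_index, subject_id = subject_id,
                label = class_id)
}

#' Generate a full labelled bundle
#'
#' Classes are balanced within each subject (trial `t` of a subject gets
#' class `((t - 1) mod n_classes) + 1`); the whole stream is deterministic
#' under `cfg$seed`. Note one 62 x 12000 trial is ~6 MB; for large corpora
#' prefer the streaming [synthetic_features()].
#'
#' @param cfg a [synthetic_config()].
#' @return A [dataset_bundle()].
#' @export
generate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_classes <- length(cfg$class_band_power)
  recs <- list(); labels <- integer(0); subjects <- integer(0)
  for (s in seq_len(cfg$n_subjects)) {
    for (t in seq_len(cfg$trials_per_subject)) {
      cl <- ((t - 1L) %% n_classes) + 1L
      recs[[length(recs) + 1L]] <- generate_trial(cfg, cl, s, t)
      labels <- c(labels, cl)
      subjects <- c(subjects, s)
    }
  }
  dataset_bundle(recs, labels, subjects, "custom")
}

#' Streamed feature extraction for a synthetic corpus
#'
#' Generates each trial, projects it onto the energy sequence, extracts the
#' windowed features and discards the raw signal, so arbitrarily large
#' corpora fit in memory. Identical output to
#' `bundle_features(generate_bundle(cfg), ...)`.
#'
#' @param cfg a [synthetic_config()].
#' @inheritParams bundle_features
#' @param progress print a dot per trial.
#' @return List with `features` (a [feature_tensor()]), `labels`, `subjects`.
#' @export
synthetic_features <- function(cfg, weights = "uniform",
                               spec = window_spec(),
                               inventory = default_inventory(),
                               params = feature_params(),
                               progress = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_classes <- length(cfg$class_band_power)
  tensors <- list(); labels <- integer(0); subjects <- integer(0)
  for (s in seq_len(cfg$n_subjects)) {
    for (t in seq_len(cfg$trials_per_subject)) {
      cl <- ((t - 1L) %% n_classes) + 1L
      rec <- generate_trial(cfg, cl, s, t)
      tensors[[length(tensors) + 1L]] <-
        extract_feature_set(energy_sequence(rec, weights), spec, inventory,
                            params)
      labels <- c(labels, cl)
      subjects <- c(subjects, s)
      if (progress) cat(".")
    }
  }
  if (progress) cat("\n")
  list(features = stack_feature_tensors(tensors), labels = labels,
       subjects = subjects)
}

#' Add iid Gaussian noise to every channel sample
#'
#' @param rec an [eeg_recording()].
#' @param sd noise SD (`sd = 0` returns the recording unchanged).
#' @param seed RNG seed.
#' @return The noisy [eeg_recording()].
#' @export
add_channel_noise <- function(rec, sd, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (sd < 0) stop_validation("sd must be nonnegative")
  if (sd == 0) return(rec)
  noisy <- .with_seed(.derive_seed(seed, 104729), {
    rec$data + matrix(rnorm(length(rec$data)) * sd,
                      nrow(rec$data), ncol(rec$data))
  })
  eeg_recording(noisy, fs = rec$fs, channel_names = rec$channel_names,
                trial_id = rec$trial_id, subject_id = rec$subject_id,
                label = rec$label)
}
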