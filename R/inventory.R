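# The default 49-entry feature inventory. The printed feature count (49) is
# never enumerated at the source; this reconstruction is one consistent
# reading: 9 time-domain + 15 Hjorth (3 x 5 bands) + 10 AR-spectrum
# (2 x 5 bands) + 15 dynamical (ApEn, 8 wavelet entropies, 6 band DEs).

#' Default feature inventory
#'
#' @return Character vector of the 49 default feature names, in extraction
#'   order.
#' @export
default_inventory <- function() {
  c("mean", "sd", "diff1", "diff1_norm", "diff2", "diff2_norm",
    "nsi", "energy", "fd",
    as.vector(t(outer(.band_names_hjorth, c("hjorth_activity_",
                                            "hjorth_mobility_",
                                            "hjorth_complexity_"),
                      function(b, p) paste0(p, b)))),
    as.vector(t(outer(.band_names_hjorth, c("sp_maxfreq_", "sp_powsum_"),
                      function(b, p) paste0(p, b)))),
    "apen", "we_a6", paste0("we_d", 1:6), "we_total",
    paste0("de_", .band_names_de))
}

#' Feature extraction parameters
#'
#' Tunables of the per-window feature computations, with the package
#' defaults: 20 NSI segments, Higuchi `k_max = 8`, ApEn `m = 2` with
#' tolerance `0.2 * sd(window)`, AR order 10 on a 512-point spectral grid.
#'
#' @param nsi_segments,fd_kmax,apen_m,apen_r_factor,ar_order,ar_grid see
#'   description.
#' @return A named list of class `feature_params`.
#' @export
feature_params <- function(nsi_segments = 20L, fd_kmax = 8L, apen_m = 2L,
                           apen_r_factor = 0.2, ar_order = 10L,
                           ar_grid = 512L) {
  structure(list(nsi_segments = nsi_segments, fd_kmax = fd_kmax,
                 apen_m = apen_m, apen_r_factor = apen_r_factor,
                 ar_order = ar_order, ar_grid = ar_grid),
            class = "feature_params")
}

# All features of one window, as a named vector over the full default
# inventory; flags from the per-family computations are collected into the
# "flags" attribute.
window_features <- function(x, fs, params = feature_params()) {
  flags <- character(0)
  grab <- function(v) {
    flags <<- c(flags, attr(v, "flags"))
    v
  }
  td <- grab(time_domain_features(x, params$nsi_segments, params$fd_kmax))
  hj <- unlist(lapply(.band_names_hjorth, function(bn) {
    h <- grab(hjorth_band(x, bn, fs))
    stats::setNames(h, paste0(c("hjorth_activity_", "hjorth_mobility_",
                                "hjorth_complexity_"), bn))
  }))
  sp <- grab(ar_spectrum_features(x, fs, p = params$ar_order,
                                  n_grid = params$ar_grid))
  ae <- approximate_entropy(x, m = params$apen_m,
                            r = params$apen_r_factor * .popsd(x))
  we <- grab(wavelet_entropy(x))
  de <- vapply(.band_names_de,
               function(bn) as.numeric(grab(differential_entropy(x, bn, fs))),
               0)
  out <- c(td, hj, sp, apen = ae, we, stats::setNames(de, paste0("de_", .band_names_de)))
  stopifnot(identical(names(out), default_inventory()))
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Extract the dynamic energy feature set
#'
#' Slices the energy sequence into moving windows and computes the feature
#' inventory on each window, giving one row per window in window order.
#' For one 60-s trial under the default 4-s/2-s windowing this is a
#' `1 x 29 x 49` tensor.
#'
#' @param es an [energy_sequence()].
#' @param spec a [window_spec()].
#' @param inventory character vector of feature names (default the full
#'   49-entry inventory); must be a subset of `default_inventory()`.
#' @param params a [feature_params()].
#' @return A [feature_tensor()] with one trial; per-window flags (if any) are
#'   stored in `provenance$flags` keyed by window.
#' @export
extract_feature_set <- function(es, spec = window_spec(),
                                inventory = default_inventory(),
                                params = feature_params()) {
  stopifnot(inherits(es, "energy_sequence"))
  inventory <- as.character(inventory)
  if (!length(inventory)) stop_validation("inventory must be nonempty")
  unknown <- setdiff(inventory, default_inventory())
  if (length(unknown))
    stop_validation(sprintf("unknown features: %s; available: %s",
                            paste(unknown, collapse = ", "),
                            paste(default_inventory(), collapse = ", ")))
  wins <- slide_windows(es, spec)
  flags <- list()
  rows <- vapply(seq_along(wins), function(i) {
    v <- window_features(wins[[i]], es$fs, params)
    fl <- attr(v, "flags")
    if (length(fl)) flags[[as.character(i)]] <<- fl
    v[inventory]
  }, numeric(length(inventory)))
  vals <- array(t(rows), c(1L, length(wins), length(inventory)))
  feature_tensor(vals, inventory, window_spec = spec,
                 provenance = list(fs = es$fs, weighting = es$weighting,
                                   flags = flags))
}

#' Stack single-trial feature tensors into one bundle tensor
#'
#' @param tensors list of [feature_tensor()] objects with identical window
#'   and feature axes.
#' @return A [feature_tensor()] with `length(tensors)` (or the summed) trials.
#' @export
stack_feature_tensors <- function(tensors) {
  stopifnot(length(tensors) > 0,
            all(vapply(tensors, inherits, TRUE, "feature_tensor")))
  fn <- tensors[[1L]]$feature_names
  dims <- vapply(tensors, function(t) dim(t$values)[2:3], integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != length(fn)))
    stop_validation("tensors have mismatching window/feature axes")
  vals <- do.call(abind3, lapply(tensors, `[[`, "values"))
  feature_tensor(vals, fn, window_spec = tensors[[1L]]$window_spec,
                 provenance = tensors[[1L]]$provenance)
}

# minimal 3-d rbind along trials
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1L], 0L)), d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1L]
    if (n) out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}

# Named subsets: the 17 top SEED features and the 19 DEAP features (the SEED
# set plus wavelet entropy of the gamma-covering component and the full-band
# spectral power sum). The two "time-domain Hjorth" entries are mapped to the
# gamma band so the 17 columns are distinct inventory entries.
.seed17 <- c("diff1", "diff1_norm", "diff2", "diff2_norm", "nsi", "fd",
             "hjorth_mobility_gamma", "hjorth_complexity_gamma",
             "hjorth_mobility_beta", "hjorth_mobility_all",
             "hjorth_complexity_beta", "hjorth_complexity_all",
             "sp_maxfreq_beta", "sp_maxfreq_all",
             "de_gamma", "de_all", "we_total")
.deap19 <- c(.seed17, "we_d2", "sp_powsum_all")

#' Select a named feature subset
#'
#' `"seed17"` is the 17-feature subset reported as most informative for the
#' 62-channel 3-class corpus (8 time-domain, 6 frequency, 3 dynamical);
#' `"deap19"` adds the wavelet entropy of the gamma-covering detail
#' component (D2 at 200 Hz) and the full-band spectral power sum. A custom
#' character vector selects arbitrary columns.
#'
#' @param tensor a [feature_tensor()].
#' @param subset `"seed17"`, `"deap19"`, or a character vector of feature
#'   names.
#' @return A [feature_tensor()] with the requested columns, in subset order.
#' @export
select_named_features <- function(tensor, subset) {
  stopifnot(inherits(tensor, "feature_tensor"))
  names_wanted <- if (identical(subset, "seed17")) .seed17
    else if (identical(subset, "deap19")) .deap19
    else as.character(subset)
  missing <- setdiff(names_wanted, tensor$feature_names)
  if (length(missing))
    stop_validation(sprintf("unknown features: %s; available: %s",
                            paste(missing, collapse = ", "),
                            paste(tensor$feature_names, collapse = ", ")))
  idx <- match(names_wanted, tensor$feature_names)
  feature_tensor(tensor$values[, , idx, drop = FALSE], names_wanted,
                 window_spec = tensor$window_spec,
                 provenance = tensor$provenance)
}
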