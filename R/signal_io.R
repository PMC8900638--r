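#' Read a multichannel recording
#'
#' Reads an EEG trial from EDF, CSV or HDF5 into an [eeg_recording()].
#'
#' The CSV dialect is one column per channel with channel names in the first
#' row and one row per sample; CSV carries no sampling rate, so `fs` is
#' required. HDF5 files use datasets `/data` (channels x samples) and
#' `/channel_names` with an `fs` attribute on `/data`. For EDF the sampling
#' rate comes from the header.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"`, `"csv"` or `"hdf5"`.
#' @param fs sampling rate in Hz; required for CSV, ignored when the format
#'   carries its own.
#' @return An [eeg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv", "hdf5"),
                           fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  switch(format,
    edf = read_edf(path),
    csv = {
      if (is.null(fs))
        stop_config("CSV carries no sampling rate: supply `fs`")
      df <- tryCatch(read.csv(path, check.names = FALSE),
                     error = function(e) stop_io(sprintf(
                       "cannot parse CSV '%s': %s", path, conditionMessage(e))))
      if (!ncol(df)) stop_io(sprintf("CSV '%s' has no columns", path))
      eeg_recording(t(as.matrix(df)), fs = fs, channel_names = names(df))
    },
    hdf5 = {
      data <- rhdf5::h5read(path, "data")
      ch <- as.character(rhdf5::h5read(path, "channel_names"))
      at <- rhdf5::h5readAttributes(path, "data")
      if (is.null(at$fs)) stop_io(sprintf("HDF5 '%s': no fs attribute", path))
      eeg_recording(data, fs = as.numeric(at$fs), channel_names = ch)
    })
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    edf = "edf", csv = "csv",
    h5 = , hdf5 = , hdf = "hdf5",
    stop_config(sprintf("cannot infer format from extension '.%s'", ext)))
}

#' Write a multichannel recording
#'
#' @param rec an [eeg_recording()].
#' @inheritParams read_recording
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            format = c("auto", "edf", "csv", "hdf5")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  switch(format,
    edf = write_edf(rec, path),
    csv = {
      df <- as.data.frame(t(rec$data))
      names(df) <- rec$channel_names
      write.csv(df, path, row.names = FALSE)
    },
    hdf5 = {
      if (file.exists(path)) unlink(path)
      rhdf5::h5createFile(path)
      rhdf5::h5write(rec$data, path, "data")
      rhdf5::h5write(rec$channel_names, path, "channel_names")
      fid <- rhdf5::H5Fopen(path)
      did <- rhdf5::H5Dopen(fid, "data")
      rhdf5::h5writeAttribute(rec$fs, did, "fs")
      rhdf5::H5Dclose(did)
      rhdf5::H5Fclose(fid)
    })
  invisible(path)
}

#' Write a feature tensor to disk
#'
#' CSV output holds one row per (trial, window) with `trial` and `window` key
#' columns followed by one named column per feature (values at >= 15
#' significant digits). HDF5 output stores the full-precision array under
#' `/values` plus `/feature_names`.
#'
#' @param tensor a [feature_tensor()].
#' @param path output file.
#' @param format `"auto"`, `"csv"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @seealso [read_feature_table()]
#' @export
write_feature_table <- function(tensor, path,
                                format = c("auto", "csv", "hdf5")) {
  stopifnot(inherits(tensor, "feature_tensor"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  v <- tensor$values
  d <- dim(v)
  if (format == "csv") {
    nr <- d[1L] * d[2L]
    keys <- expand.grid(window = seq_len(d[2L]), trial = seq_len(d[1L]))
    flat <- matrix(aperm(v, c(2L, 1L, 3L)), nrow = nr, ncol = d[3L])
    cells <- matrix(sprintf("%.15g", flat), nrow = nr, ncol = d[3L])
    out <- data.frame(trial = keys$trial, window = keys$window,
                      cells, stringsAsFactors = FALSE,
                      check.names = FALSE)
    names(out) <- c("trial", "window", tensor$feature_names)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(v, path, "values")
    rhdf5::h5write(tensor$feature_names, path, "feature_names")
  }
  invisible(path)
}

#' Read a feature tensor written by [write_feature_table()]
#'
#' @inheritParams write_feature_table
#' @return A [feature_tensor()].
#' @export
read_feature_table <- function(path, format = c("auto", "csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE)
    fn <- setdiff(names(df), c("trial", "window"))
    if (!nrow(df))
      return(feature_tensor(array(0, c(0L, 0L, length(fn))), fn))
    nt <- max(df$trial); nw <- max(df$window)
    v <- array(NA_real_, c(nt, nw, length(fn)))
    for (j in seq_along(fn))
      v[cbind(df$trial, df$window, j)] <- df[[fn[j]]]
    feature_tensor(v, fn)
  } else {
    v <- rhdf5::h5read(path, "values")
    fn <- as.character(rhdf5::h5read(path, "feature_names"))
    feature_tensor(v, fn)
  }
}
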