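# Minimal EDF (European Data Format) support: 256-byte ASCII main header,
# 256 bytes per signal, then data records of 16-bit little-endian integers
# mapped linearly from the digital to the physical range. Only what the
# package needs: equal sampling rate across signals, no annotations.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, space padded
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  .edf_pad(s, width)
}

write_edf <- function(rec, path) {
  n_sig <- n_channels(rec)
  n_samp <- n_samples(rec)
  # one data record per second when fs divides the length evenly,
  # otherwise a single record spanning the whole signal
  if (abs(rec$fs - round(rec$fs)) < 1e-9 && n_samp %% round(rec$fs) == 0) {
    spr <- round(rec$fs); dur <- 1; n_rec <- n_samp %/% spr
  } else {
    spr <- n_samp; dur <- n_samp / rec$fs; n_rec <- 1L
  }
  pmin <- apply(rec$data, 1L, min)
  pmax <- apply(rec$data, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("X", 80), .edf_pad("X", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + n_sig), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_num(dur, 8), .edf_pad(n_sig, 4))
  sig_hdr <- paste0(
    paste(vapply(rec$channel_names, .edf_pad, "", 16L), collapse = ""),
    paste(rep(.edf_pad("", 80), n_sig), collapse = ""),
    paste(rep(.edf_pad("uV", 8), n_sig), collapse = ""),
    paste(vapply(pmin, .edf_num, "", 8L), collapse = ""),
    paste(vapply(pmax, .edf_num, "", 8L), collapse = ""),
    paste(rep(.edf_pad(dmin, 8), n_sig), collapse = ""),
    paste(rep(.edf_pad(dmax, 8), n_sig), collapse = ""),
    paste(rep(.edf_pad("", 80), n_sig), collapse = ""),
    paste(rep(.edf_pad(spr, 8), n_sig), collapse = ""),
    paste(rep(.edf_pad("", 32), n_sig), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((rec$data - pmin) * scale + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) as.numeric(trimws(rd(n)))
  if (trimws(rd(8)) != "0") stop_io(sprintf("'%s' is not an EDF file", path))
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes (recomputed from n_sig)
  rd(44)
  n_rec <- num(8); dur <- num(8); n_sig <- as.integer(num(4))
  if (is.na(n_sig) || n_sig < 1L) stop_io("EDF header: bad signal count")
  field <- function(w) vapply(seq_len(n_sig), function(i) rd(w), "")
  labels <- trimws(field(16)); field(80); field(8)
  pmin <- as.numeric(trimws(field(8))); pmax <- as.numeric(trimws(field(8)))
  dmin <- as.numeric(trimws(field(8))); dmax <- as.numeric(trimws(field(8)))
  field(80)
  spr <- as.integer(trimws(field(8))); field(32)
  if (length(unique(spr)) != 1L)
    stop_io("EDF with per-signal sampling rates is not supported")
  spr1 <- spr[1L]
  fs <- spr1 / dur
  data <- matrix(0, n_sig, n_rec * spr1)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = n_sig * spr1, size = 2L,
                   endian = "little", signed = TRUE)
    if (length(raw) < n_sig * spr1) stop_io("EDF file truncated")
    block <- matrix(raw, nrow = spr1, ncol = n_sig)  # signal-major in file
    data[, ((r - 1L) * spr1 + 1L):(r * spr1)] <- t(block)
  }
  phys <- (data - dmin) * (pmax - pmin) / (dmax - dmin) + pmin
  eeg_recording(phys, fs = fs, channel_names = labels)
}
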