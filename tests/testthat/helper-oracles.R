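# Independent brute-force oracles and tiny fixtures. These deliberately use
# naive R implementations (double loops, direct formulas) so they share no
# code path with the package.

apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1
    emb <- sapply(seq_len(mm), function(k) x[k:(k + nv - 1)])
    if (nv == 1) emb <- matrix(emb, nrow = 1)
    cnt <- sapply(seq_len(nv), function(i)
      sum(apply(abs(sweep(emb, 2, emb[i, ], "-")), 1, max) < r))
    mean(log(cnt / nv))
  }
  phi(m) - phi(m + 1)
}

higuchi_oracle <- function(x, k_max = 8L) {
  n <- length(x)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lmk <- numeric(k)
    for (m in seq_len(k)) {
      nk <- floor((n - m) / k)
      s <- 0
      for (i in seq_len(nk))
        s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      lmk[m] <- s * (n - 1) / (nk * k^2)
    }
    lk[k] <- mean(lmk)
  }
  fit <- stats::lm(log(lk) ~ log(seq_len(k_max)))
  -unname(coef(fit)[2])
}

nsi_oracle <- function(x, m = 20L) {
  seg <- length(x) %/% m
  means <- numeric(m)
  for (i in seq_len(m))
    means[i] <- mean(x[((i - 1) * seg + 1):(i * seg)])
  sqrt(mean((means - mean(means))^2))
}

mi_oracle <- function(X, bins) {
  m <- nrow(X); n <- ncol(X)
  bin_idx <- function(col) {
    rng <- range(col)
    if (diff(rng) <= 0) return(rep(1L, m))
    pmin(floor((col - rng[1]) / diff(rng) * bins) + 1, bins)
  }
  B <- sapply(seq_len(n), function(j) bin_idx(X[, j]))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  I <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) {
      p <- table(factor(B[, j], levels = 1:bins)) / m
      I[j, k] <- ent(as.numeric(p))
    } else {
      acc <- 0
      for (a in seq_len(bins)) for (b in seq_len(bins)) {
        pab <- sum(B[, j] == a & B[, k] == b) / m
        if (pab > 0) {
          pa <- sum(B[, j] == a) / m
          pb <- sum(B[, k] == b) / m
          acc <- acc + pab * log(pab / (pa * pb))
        }
      }
      I[j, k] <- acc
    }
  }
  I
}

# Direct DFT band mask, written independently of the package.
bandpass_oracle <- function(x, lo, hi, fs) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f2 <- pmin(f, fs - f)
  X <- fft(x)
  X[!(f2 >= lo & f2 <= hi)] <- 0+0i
  Re(fft(X, inverse = TRUE) / n)
}

# Independent minimal EDF writer: fixed-width ASCII header fields written
# byte by byte, one data record per file.
edf_oracle_write <- function(path, data, fs, labels) {
  ns <- nrow(data); nt <- ncol(data)
  pad <- function(s, w) sprintf("%-*s", w, substr(s, 1, w))
  pmin_ <- apply(data, 1, min) - 1e-9
  pmax_ <- apply(data, 1, max) + 1e-9
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("pat", 80), pad("rec", 80),
                pad("02.03.21", 8), pad("10.00.00", 8),
                pad(as.character(256 * (1 + ns)), 8), pad("", 44),
                pad("1", 8), pad(format(nt / fs), 8), pad(as.character(ns), 4))
  sig <- paste0(paste(sapply(labels, pad, 16), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad("uV", 8), ns), collapse = ""),
                paste(sapply(format(pmin_, digits = 6), pad, 8), collapse = ""),
                paste(sapply(format(pmax_, digits = 6), pad, 8), collapse = ""),
                paste(rep(pad("-32768", 8), ns), collapse = ""),
                paste(rep(pad("32767", 8), ns), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad(as.character(nt), 8), ns), collapse = ""),
                paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((data[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

# Small reusable fixtures -------------------------------------------------

tiny_recording <- function(n_ch = 3, n_samp = 400, fs = 100, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * n_samp), n_ch), fs = fs)
}

small_bundle_features <- function(seed = 11) {
  cfg <- synthetic_config(n_subjects = 3L, trials_per_subject = 10L,
                          duration_s = 12, seed = seed)
  synthetic_features(cfg, spec = window_spec(4, 2))
}

tiny_net_spec <- function(n_feat = 17L, seq_len = 5L, n_classes = 2L,
                          epochs = 12L, seed = 3L) {
  network_spec(input_size = n_feat, n_classes = n_classes, seq_len = seq_len,
               bilstm_units = 16L, lstm_units = 8L, dense_units = 16L,
               epochs = epochs, seed = seed)
}
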