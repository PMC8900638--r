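test_that("time-domain statistics match their printed forms", {
  v <- time_domain_features(c(1, 2, 3, 4))
  expect_equal(unname(v["mean"]), 2.5)
  expect_equal(unname(v["diff1"]), 1.0)
  expect_equal(unname(v["energy"]), 30)
  # population SD
  expect_equal(unname(time_domain_features(c(1, 3, 1, 3))["sd"]), 1.0)
  # constant window: normalized differentials 0, FD 1, both flagged
  vc <- time_domain_features(rep(2, 100))
  expect_equal(unname(vc[c("diff1_norm", "diff2_norm")]), c(0, 0))
  expect_equal(unname(vc["fd"]), 1.0)
  expect_true(length(attr(vc, "flags")) >= 2)
})

test_that("Higuchi FD: a straight line has dimension ~1, oracle agreement", {
  ramp <- seq(0, 1, length.out = 800)
  fd <- unname(time_domain_features(ramp)["fd"])
  expect_gte(fd, 1.0 - 1e-9)
  expect_lte(fd, 1.05)
  set.seed(21)
  for (i in 1:5) {
    x <- cumsum(rnorm(100 + 20 * i))
    expect_equal(higuchi_fd(x), higuchi_oracle(x), tolerance = 1e-10)
  }
})

test_that("NSI and ApEn match brute-force oracles", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(200)
    expect_equal(nsi(x), nsi_oracle(x), tolerance = 1e-10)
    expect_equal(approximate_entropy(x, 2, 0.25),
                 apen_oracle(x, 2, 0.25), tolerance = 1e-10)
  }
  # periodic alternating series, m = 2, r = 0.5
  z <- rep(c(0, 1), 100)
  expect_lt(abs(approximate_entropy(z, 2, 0.5) - apen_oracle(z, 2, 0.5)),
            1e-12)
  expect_lt(approximate_entropy(z, 2, 0.5), 1e-3)  # near-perfect regularity
  expect_equal(approximate_entropy(rep(5, 60)), 0)
  expect_error(approximate_entropy(rnorm(50), r = -1),
               class = "dynergy_parameter_error")
})

test_that("Hjorth parameters: direct-formula oracle and known cases", {
  fs <- 200
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t) + 0.1 * sin(2 * pi * 25 * t)
  h <- hjorth_band(x, "alpha", fs)
  # oracle: direct formulas on independently band-passed samples
  y <- bandpass_oracle(x, 8, 13, fs)
  pv <- function(z) mean((z - mean(z))^2)
  mo <- sqrt(pv(diff(y) * fs) / pv(y))
  co <- sqrt(pv(diff(diff(y) * fs) * fs) / pv(diff(y) * fs)) / mo
  expect_equal(unname(h["activity"]), pv(y), tolerance = 1e-9)
  expect_equal(unname(h["mobility"]), mo, tolerance = 1e-9)
  expect_equal(unname(h["complexity"]), co, tolerance = 1e-9)
  # mobility of a pure sinusoid ~ its angular frequency (discrete-diff form)
  expect_equal(unname(h["mobility"]), 2 * fs * sin(pi * 10 / fs),
               tolerance = 1e-2)
  hc <- hjorth_band(rep(1, 800), "alpha", fs)
  expect_equal(unname(hc), c(0, 0, 0), ignore_attr = TRUE)
  expect_match(attr(hc, "flags"), "zero_variance")
})

test_that("white noise is more complex than a tone in the same band", {
  fs <- 200
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t)
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    noise <- rnorm(length(t))
    hjorth_band(noise, "alpha", fs)["complexity"] >
      hjorth_band(tone, "alpha", fs)["complexity"]
  }, TRUE)
  expect_gt(mean(wins), 0.5)
})

test_that("AR spectrum locates peaks and scales quadratically", {
  fs <- 200
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  set.seed(2)
  x <- sin(2 * pi * 20 * t) + 0.01 * rnorm(length(t))
  sp <- ar_spectrum_features(x, fs)
  expect_lt(abs(sp[["sp_maxfreq_beta"]] - 20), 0.5)
  # flat spectrum of white noise: full-band sum ~ grid size * variance
  set.seed(3)
  w <- rnorm(800)
  spw <- ar_spectrum_features(w, fs)
  expect_lt(abs(spw[["sp_powsum_all"]] - 512 * var(w)) / (512 * var(w)), 0.2)
  # homogeneity: scaling by c multiplies every power sum by c^2
  sp2 <- ar_spectrum_features(3 * w, fs)
  sums <- grep("powsum", names(spw))
  expect_equal(unname(sp2[sums]), unname(9 * spw[sums]), tolerance = 1e-8)
  expect_equal(sp2[["sp_maxfreq_all"]], spw[["sp_maxfreq_all"]])
})

test_that("wavelet entropy: degenerate, uniform and ordering cases", {
  # constant signal: all energy in the approximation -> total WE = 0
  wc <- wavelet_entropy(rep(3.7, 768))
  expect_equal(unname(wc["we_total"]), 0, tolerance = 1e-12)
  # equal component energies -> total WE = ln 7
  eq <- wavelet_entropy_from_coeffs(list(a6 = c(1, 1), d1 = c(sqrt(2)),
                                         d2 = c(1, -1), d3 = sqrt(2),
                                         d4 = c(1, 1), d5 = sqrt(2),
                                         d6 = c(-1, 1)))
  expect_equal(unname(eq["total"]), log(7), tolerance = 1e-12)
  # orthonormality: periodized db4 conserves energy on dyadic lengths
  set.seed(8)
  x <- rnorm(768)
  dec <- wavelet_decompose(x)
  expect_equal(sum(unlist(dec)^2), sum(x^2), tolerance = 1e-10)
  # white noise spreads energy across scales more than a tone
  fs <- 200
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone_we <- wavelet_entropy(sin(2 * pi * 10 * t))["we_total"]
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    wavelet_entropy(rnorm(800))["we_total"] > tone_we
  }, TRUE)
  expect_gt(mean(wins), 0.5)
})

test_that("differential entropy closed forms and log identity", {
  set.seed(12)
  x <- rnorm(800)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # unit population var
  expect_equal(differential_entropy(x, "all", 200), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  x0 <- x * sqrt(1 / (2 * pi * exp(1)))
  expect_equal(differential_entropy(x0, "all", 200), 0, tolerance = 1e-12)
  # scaling by c adds ln|c|
  de1 <- differential_entropy(x, "beta", 200)
  de2 <- differential_entropy(2.5 * x, "beta", 200)
  expect_equal(de2 - de1, log(2.5), tolerance = 1e-10)
  flat <- differential_entropy(rep(1, 400), "beta", 200)
  expect_lt(flat, -300)
  expect_match(attr(flat, "flags"), "zero_variance")
})

test_that("extraction produces the default 1 x 29 x 49 tensor deterministically", {
  rec <- tiny_recording(3, 12000, fs = 200, seed = 4)
  es <- energy_sequence(rec)
  ft <- extract_feature_set(es)
  expect_equal(dim(ft), c(1L, 29L, 49L))
  expect_identical(ft$feature_names, default_inventory())
  expect_true(all(is.finite(ft$values)))
  # restricted inventory: values equal per-window means
  fm <- extract_feature_set(es, inventory = "mean")
  expect_equal(dim(fm), c(1L, 29L, 1L))
  wins <- slide_windows(es)
  expect_equal(as.numeric(fm$values[1, , 1]), vapply(wins, mean, 0))
  # determinism
  expect_identical(extract_feature_set(es)$values, ft$values)
  expect_error(extract_feature_set(es, inventory = "nope"),
               class = "dynergy_validation_error")
})

test_that("named subsets have the reference sizes and column order", {
  rec <- tiny_recording(3, 2400, fs = 200, seed = 5)
  ft <- extract_feature_set(energy_sequence(rec))
  s17 <- select_named_features(ft, "seed17")
  expect_equal(dim(s17)[3], 17L)
  d19 <- select_named_features(ft, "deap19")
  expect_equal(dim(d19)[3], 19L)
  expect_identical(d19$feature_names[1:17], s17$feature_names)
  one <- select_named_features(ft, "mean")
  expect_equal(dim(one)[3], 1L)
  expect_equal(one$values[1, , 1], ft$values[1, , 1])
  err <- tryCatch(select_named_features(ft, "bogus"), error = identity)
  expect_s3_class(err, "dynergy_validation_error")
  expect_match(conditionMessage(err), "available")
})

test_that("feature covariances follow each formula (property)", {
  set.seed(77)
  fs <- 200
  for (i in 1:5) {
    x <- rnorm(800)
    c_shift <- runif(1, -5, 5)
    c_scale <- runif(1, 0.5, 4)
    v0 <- time_domain_features(x)
    vs <- time_domain_features(x + c_shift)
    vm <- time_domain_features(x * c_scale)
    expect_equal(unname(vs["mean"]), unname(v0["mean"]) + c_shift,
                 tolerance = 1e-9)
    expect_equal(unname(vs[c("sd", "diff1", "diff2", "nsi")]),
                 unname(v0[c("sd", "diff1", "diff2", "nsi")]),
                 tolerance = 1e-9)
    expect_equal(unname(vm[c("sd", "diff1", "diff2", "nsi")]),
                 unname(c_scale * v0[c("sd", "diff1", "diff2", "nsi")]),
                 tolerance = 1e-9)
    expect_equal(unname(vm["energy"]), unname(c_scale^2 * v0["energy"]),
                 tolerance = 1e-9)
    expect_equal(unname(vm[c("diff1_norm", "diff2_norm")]),
                 unname(v0[c("diff1_norm", "diff2_norm")]), tolerance = 1e-9)
    expect_equal(differential_entropy(c_scale * x, "alpha", fs) -
                   differential_entropy(x, "alpha", fs),
                 log(c_scale), tolerance = 1e-9)
  }
})
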