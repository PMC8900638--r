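test_that("CSV recordings round-trip with named channels", {
  rec <- eeg_recording(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), nrow = 2,
                              byrow = TRUE),
                       fs = 4, channel_names = c("FP1", "FP2"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, p)
  back <- read_recording(p, fs = 4)
  expect_equal(dim(back$data), c(2L, 4L))
  expect_equal(back$channel_names, c("FP1", "FP2"))
  expect_equal(unname(back$data), unname(rec$data), tolerance = 1e-12)
  expect_error(read_recording(p), class = "dynergy_config_error")
})

test_that("HDF5 recordings round-trip bit-identically", {
  rec <- tiny_recording(4, 200, fs = 128, seed = 2)
  p <- withr::local_tempfile(fileext = ".h5")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_identical(unname(back$data), unname(rec$data))
  expect_identical(back$fs, 128)
  expect_identical(back$channel_names, rec$channel_names)
})

test_that("EDF files from an independent writer parse with header fs", {
  set.seed(5)
  data <- matrix(rnorm(2 * 400, sd = 50), 2)
  p <- withr::local_tempfile(fileext = ".edf")
  edf_oracle_write(p, data, fs = 200, labels = c("C3", "C4"))
  rec <- read_recording(p)
  expect_equal(rec$fs, 200)
  expect_equal(n_samples(rec), 400L)
  expect_equal(rec$channel_names, c("C3", "C4"))
  # 16-bit quantization over the value range
  expect_lt(max(abs(rec$data - data)), diff(range(data)) / 65535 * 2)
  # package writer -> package reader
  rec2 <- eeg_recording(data, fs = 200, channel_names = c("C3", "C4"))
  p2 <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec2, p2)
  back <- read_recording(p2)
  expect_equal(back$fs, 200)
  expect_lt(max(abs(back$data - data)), diff(range(data)) / 65535 * 2)
})

test_that("unreadable and invalid inputs raise typed errors", {
  expect_error(read_recording(file.path(tempdir(), "nope.csv"), fs = 1),
               class = "dynergy_io_error")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "NaN,3"), p)
  expect_error(read_recording(p, fs = 10), regexp = "'a'",
               class = "dynergy_validation_error")
})

test_that("built-in region presets reproduce the montage division", {
  w <- load_region_weighting(dataset = "seed")
  expect_length(w$region_of_channel, 62L)
  r1 <- names(w$region_of_channel)[w$region_of_channel == 1]
  expect_true(all(c("FP1", "AF3", "F7") %in% r1))
  expect_equal(unname(w$region_sum[["1"]]), 0.4)
  expect_equal(sum(w$region_sum), 1)
  d <- load_region_weighting(dataset = "deap")
  expect_length(d$region_of_channel, 32L)
  r4 <- names(d$region_of_channel)[d$region_of_channel == 4]
  expect_setequal(r4, c("CP2", "CP6", "P4", "P8", "PO4", "O2", "C4", "T8"))
  expect_equal(unname(d$region_sum[["4"]]), 0.1)
  # each channel in exactly one region (map structure guarantees it)
  expect_false(anyDuplicated(names(w$region_of_channel)) > 0)
  expect_false(anyDuplicated(names(d$region_of_channel)) > 0)
})

test_that("custom weighting configs are validated", {
  expect_silent(region_weighting(c(a = 1, b = 1, c = 2, d = 2),
                                 c(`1` = 0.5, `2` = 0.5, `3` = 0, `4` = 0)))
  expect_error(region_weighting(c(a = 1, b = 2), c(`1` = 0.5, `2` = 0.4)),
               class = "dynergy_validation_error")
  p <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# montage", "C3=1", "C4=2", "O1=3", "O2=4",
               "region_sum.1=0.4", "region_sum.2=0.3",
               "region_sum.3=0.2", "region_sum.4=0.1"), p)
  w <- load_region_weighting(p)
  expect_equal(unname(w$region_of_channel[["C3"]]), 1L)
  expect_error(channel_weights(w, c("C3", "FZ")),
               class = "dynergy_validation_error")
})

test_that("feature tables round-trip through CSV and HDF5", {
  set.seed(3)
  ft <- feature_tensor(array(rnorm(1 * 2 * 3), c(1, 2, 3)),
                       c("mean", "sd", "energy"))
  pc <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, pc)
  lines <- readLines(pc)
  expect_length(lines, 3L)  # header + 2 window rows
  expect_equal(strsplit(lines[1], ",")[[1]],
               c("trial", "window", "mean", "sd", "energy"))
  back <- read_feature_table(pc)
  expect_equal(back$values, ft$values, tolerance = 1e-12)
  ph <- withr::local_tempfile(fileext = ".h5")
  write_feature_table(ft, ph)
  expect_identical(read_feature_table(ph)$values, ft$values)
  # degenerate: zero trials
  empty <- feature_tensor(array(0, c(0, 0, 2)), c("a", "b"))
  pe <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(empty, pe)
  expect_equal(nrow(read.csv(pe)), 0L)
  expect_equal(dim(read_feature_table(pe)$values)[3], 2L)
})
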