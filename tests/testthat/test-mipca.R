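test_that("value proportions implement the min-shift rule", {
  expect_equal(as.numeric(value_proportions(cbind(c(1, 3)))), c(0.25, 0.75))
  expect_equal(as.numeric(value_proportions(cbind(c(2, 2, 2)))), rep(1 / 3, 3))
  expect_equal(as.numeric(value_proportions(cbind(c(-1, 0, 1)))),
               c(0, 1 / 3, 2 / 3))
  z <- value_proportions(cbind(c(0, 0, 0)))
  expect_equal(as.numeric(z), rep(1 / 3, 3))
  expect_match(attr(z, "flags"), "zero_column")
})

test_that("feature entropy: uniform, degenerate and mixed cases", {
  expect_equal(feature_entropy(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(feature_entropy(c(1, 0, 0)), 0)
  expect_equal(feature_entropy(c(0.25, 0.75)),
               -0.25 * log(0.25) - 0.75 * log(0.75), tolerance = 1e-12)
  expect_equal(feature_entropy(c(0.25, 0.75)), 0.5623, tolerance = 1e-4)
  expect_error(feature_entropy(c(0.2, 0.2)),
               class = "dynergy_validation_error")
})

test_that("MI matrix: self-information, independence, oracle equivalence", {
  set.seed(14)
  x <- runif(400)
  X <- cbind(a = x, b = x, c = runif(400))
  M <- mutual_information_matrix(X)
  expect_equal(M[1, 2], M[1, 1], tolerance = 1e-12)  # MI(X,X) = H(X)
  expect_lt(max(abs(M - t(M))), 1e-12)
  expect_true(all(M >= -1e-10))
  # independent columns at m = 1e4: MI below 0.05 nats
  set.seed(15)
  U <- cbind(runif(1e4), runif(1e4))
  Mi <- mutual_information_matrix(U)
  expect_lt(Mi[1, 2], 0.05)
  # brute-force oracle on the same bins
  set.seed(16)
  Xs <- matrix(rnorm(150 * 4), 150)
  expect_equal(mutual_information_matrix(Xs, bins = 6),
               mi_oracle(Xs, 6), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(mutual_information_matrix(Xs[, 1, drop = FALSE]),
               class = "dynergy_validation_error")
  expect_error(mutual_information_matrix(Xs[1:10, ], bins = 6),
               class = "dynergy_validation_error")
})

test_that("eigendecomposition, contribution rates and component selection", {
  m1 <- mipca_from_mi(diag(4), cutoff = 0.95)
  expect_equal(m1$contrib, rep(0.25, 4))
  expect_equal(m1$l, 4L)
  # eigenvalues {3, 1}
  M <- matrix(c(2, 1, 1, 2), 2)
  m2 <- mipca_from_mi(M, cutoff = 0.95)
  expect_equal(m2$eigenvalues, c(3, 1))
  expect_equal(m2$contrib, c(0.75, 0.25))
  expect_equal(m2$cum_contrib, c(0.75, 1.0))
  expect_equal(m2$l, 2L)
  expect_equal(mipca_from_mi(M, cutoff = 0.75)$l, 1L)
  # reconstruction B' Lambda B
  set.seed(17)
  X <- matrix(rnorm(300 * 6), 300)
  m3 <- fit_mipca(X)
  rec <- t(m3$B) %*% diag(m3$eigenvalues) %*% m3$B
  expect_lt(max(abs(rec - m3$mi_matrix)), 1e-8)
  expect_true(all(diff(m3$cum_contrib) >= -1e-12))
  expect_equal(m3$cum_contrib[length(m3$cum_contrib)], 1, tolerance = 1e-10)
  expect_error(mipca_from_mi(matrix(c(1, 2, 0, 1), 2)),
               class = "dynergy_validation_error")
  expect_error(mipca_from_mi(diag(2) * NA),
               class = "dynergy_numeric_error")
})

test_that("raising the cutoff never decreases l (property)", {
  set.seed(18)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5)
    M <- crossprod(A)  # PSD stand-in for an MI matrix
    ls <- vapply(c(0.85, 0.90, 0.95, 1.0),
                 function(cc) mipca_from_mi(M, cc)$l, 0L)
    expect_true(all(diff(ls) >= 0))
  }
})

test_that("projection follows Z = X B_l' and linearity", {
  set.seed(19)
  X <- matrix(rnorm(120 * 4), 120)
  m <- fit_mipca(X, cutoff = 1.0)
  expect_equal(m$l, 4L)
  Z <- predict(m, X)
  expect_equal(Z, X %*% t(m$B))
  # duplicated rows duplicate outputs
  X2 <- X[c(1, 1, 2), ]
  Z2 <- predict(m, X2)
  expect_identical(Z2[1, ], Z2[2, ])
  # identity decision matrix passes X through
  m_id <- m
  m_id$B_l <- diag(4)
  expect_equal(predict(m_id, X), X)
  expect_error(predict(m, X[, 1:3]), class = "dynergy_validation_error")
})

test_that("redundant features compress, independent features do not", {
  set.seed(20)
  base <- matrix(runif(600 * 3), 600)
  dup <- cbind(base, base)  # 3 unique signals copied twice
  m_dup <- fit_mipca(dup, cutoff = 0.95)
  expect_lt(m_dup$l, ncol(dup))
  ind <- matrix(runif(600 * 6), 600)
  m_ind <- fit_mipca(ind, cutoff = 0.95)
  expect_gte(m_ind$l / ncol(ind), m_dup$l / ncol(dup))
  expect_gte(m_ind$l, 5L)
})

test_that("models serialize to HDF5 and reload equal", {
  set.seed(22)
  X <- matrix(rnorm(200 * 4), 200)
  m <- fit_mipca(X, cutoff = 0.9)
  p <- withr::local_tempfile(fileext = ".h5")
  write_mipca(m, p)
  back <- read_mipca(p)
  expect_equal(back$eigenvalues, m$eigenvalues, tolerance = 1e-12)
  expect_equal(back$B_l, m$B_l, tolerance = 1e-12)
  expect_equal(back$l, m$l)
})
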