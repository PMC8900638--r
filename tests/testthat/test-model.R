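test_that("network spec validation and output widths", {
  s3 <- network_spec(input_size = 17, n_classes = 3)
  expect_equal(nrow(build_network(s3)$params$W_d2), 3L)
  s2 <- network_spec(input_size = 19, n_classes = 2)
  expect_equal(nrow(build_network(s2)$params$W_d2), 2L)
  expect_error(network_spec(17, 1), class = "dynergy_validation_error")
  expect_error(network_spec(17, 2, dropout = 1),
               class = "dynergy_validation_error")
  expect_error(network_spec(0, 2), class = "dynergy_validation_error")
  expect_error(network_spec(17, 2, optimizer = "adam"),
               class = "dynergy_validation_error")
})

test_that("initialization is seed-deterministic; zero epochs is a no-op", {
  s <- tiny_net_spec(seed = 9)
  a <- build_network(s)
  b <- build_network(s)
  expect_identical(a$params, b$params)
  s2 <- tiny_net_spec(seed = 10)
  expect_false(identical(build_network(s2)$params$W_f, a$params$W_f))
  s0 <- tiny_net_spec(epochs = 0L)
  net0 <- build_network(s0)
  set.seed(1)
  X <- array(rnorm(6 * 5 * 17), c(6, 5, 17))
  fit0 <- train_network(net0, X, rep(1:2, 3))
  expect_identical(fit0$params, net0$params)
})

test_that("analytic gradients match numerical differentiation", {
  spec <- network_spec(input_size = 3, n_classes = 2, seq_len = 4,
                       bilstm_units = 3, lstm_units = 2, dense_units = 4,
                       seed = 42)
  net <- build_network(spec)
  set.seed(5)
  X <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  y <- c(0L, 1L, 0L, 1L, 1L)
  g <- dynergy:::lstm_loss_grads_cpp(net$params, X, y)
  eps <- 1e-6
  set.seed(6)
  for (pn in names(net$params)) {
    for (i in sample(length(net$params[[pn]]),
                     min(4L, length(net$params[[pn]])))) {
      p <- net$params
      p[[pn]][i] <- p[[pn]][i] + eps
      lp <- dynergy:::lstm_loss_cpp(p, X, y)
      p[[pn]][i] <- p[[pn]][i] - 2 * eps
      lm <- dynergy:::lstm_loss_cpp(p, X, y)
      numg <- (lp - lm) / (2 * eps)
      expect_lt(abs(g$grads[[pn]][i] - numg) /
                  max(1e-8, abs(numg) + abs(g$grads[[pn]][i])), 1e-5)
    }
  }
})

test_that("training reduces loss and fits separable data", {
  set.seed(3)
  n <- 60
  y <- rep(1:2, n / 2)
  X <- array(rnorm(n * 5 * 17), c(n, 5, 17))
  X[y == 2, , 1] <- X[y == 2, , 1] + 3
  fit <- train_network(tiny_net_spec(epochs = 40L), X, y)
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  expect_gte(mean(predict(fit, X) == y), 0.95)
  # deterministic under the spec seed
  fit2 <- train_network(tiny_net_spec(epochs = 40L), X, y)
  expect_identical(fit$params, fit2$params)
  expect_error(train_network(tiny_net_spec(), X, rep(1, n)),
               class = "dynergy_validation_error")
  Xbad <- X; Xbad[1] <- NA
  expect_error(train_network(tiny_net_spec(), Xbad, y),
               class = "dynergy_validation_error")
})

test_that("standardization statistics come from the training data", {
  set.seed(4)
  X <- array(rnorm(20 * 5 * 17, mean = 3, sd = 2), c(20, 5, 17))
  fit <- train_network(tiny_net_spec(epochs = 1L), X, rep(1:2, 10))
  expect_equal(fit$standardize$mean, apply(X, 3, mean))
  expect_equal(fit$standardize$sd, apply(X, 3, sd))
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  labels <- rep(1:2, 50)
  f <- stratified_folds(labels, 10, seed = 5)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10))
  for (k in 1:10) expect_equal(sum(labels[f == k] == 1), 5L)
  expect_identical(f, stratified_folds(labels, 10, seed = 5))
  expect_false(identical(f, stratified_folds(labels, 10, seed = 6)))
})

test_that("k-fold evaluation partitions trials and recovers signal", {
  sf <- small_bundle_features(seed = 11)
  feats <- select_named_features(sf$features, "seed17")
  spec <- tiny_net_spec()
  rep1 <- evaluate_kfold(NULL, spec, k = 5, features = feats,
                         labels = sf$labels)
  expect_s3_class(rep1, "evaluation_report")
  expect_length(rep1$accuracies, 5L)
  expect_equal(rep1$mean_accuracy, mean(rep1$accuracies))
  expect_gt(rep1$mean_accuracy, 0.8)
  expect_error(evaluate_kfold(NULL, spec, k = 50, features = feats,
                              labels = sf$labels),
               class = "dynergy_validation_error")
})

test_that("LOSO holds each subject out once and recovers signal", {
  sf <- small_bundle_features(seed = 11)
  feats <- select_named_features(sf$features, "seed17")
  rep1 <- evaluate_loso(NULL, tiny_net_spec(), features = feats,
                        labels = sf$labels, subjects = sf$subjects)
  expect_equal(rep1$units, as.character(unique(sf$subjects)))
  expect_length(rep1$accuracies, 3L)
  expect_gt(rep1$mean_accuracy, 0.8)
})

test_that("in-fold MIPCA reduces the network input dimension", {
  sf <- small_bundle_features(seed = 11)
  spec <- tiny_net_spec(n_feat = 49L, epochs = 4L)
  rep1 <- evaluate_kfold(NULL, spec, k = 3, features = sf$features,
                         labels = sf$labels, use_mipca = TRUE,
                         mipca_cutoff = 0.90)
  expect_length(rep1$accuracies, 3L)
  expect_true(all(rep1$accuracies >= 0 & rep1$accuracies <= 1))
})

test_that("SVM baseline: grid, separable data and shuffled labels", {
  expect_length(svm_c_grid(), 12L)
  expect_equal(svm_c_grid()[1], 2^-3)
  expect_equal(svm_c_grid()[12], 2^8)
  set.seed(4)
  n <- 80
  X <- matrix(rnorm(n * 5), n)
  y <- rep(1:2, each = n / 2)
  X[y == 2, 1] <- X[y == 2, 1] + 6
  r <- baseline_svm(X, y, seed = 1)
  expect_gte(r$accuracy, 0.95)
  set.seed(8)
  r0 <- baseline_svm(X, sample(y), seed = 1)
  expect_lt(abs(r0$accuracy - 0.5), 0.25)
  expect_error(baseline_svm(X, rep(1, n)), class = "dynergy_validation_error")
  expect_error(baseline_svm(matrix(1, 20, 3), rep(1:2, 10)),
               class = "dynergy_validation_error")
})
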