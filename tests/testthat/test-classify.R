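test_that("k = 1 prediction agrees with the exhaustive pairwise-distance oracle", {
  set.seed(51)
  x <- matrix(rnorm(50 * 4), 50, 4)
  y <- sample(c("A", "B"), 50, replace = TRUE)
  q <- matrix(rnorm(20 * 4), 20, 4)
  model <- knn_fit(x, y, k = 1)
  pred <- predict(model, q)
  oracle <- apply(q, 1, function(v) y[which.min(colSums((t(x) - v)^2))])
  expect_identical(pred, oracle)
  # a training point queries back to its own label
  expect_identical(predict(model, x[17, ]), y[17])
})

test_that("nearest-neighbour basics: proximity wins, permutations are irrelevant", {
  x <- rbind(c(0, 0), c(10, 10))
  m <- knn_fit(x, c("A", "B"), k = 1)
  expect_identical(predict(m, c(1, 1)), "A")
  set.seed(52)
  x <- matrix(rnorm(40), 20, 2)
  y <- sample(0:1, 20, replace = TRUE)
  q <- matrix(rnorm(10), 5, 2)
  perm <- sample(20)
  p1 <- predict(knn_fit(x, y, k = 3), q)
  p2 <- predict(knn_fit(x[perm, ], y[perm], k = 3), q)
  expect_equal(p1, p2)
})

test_that("exact distance ties resolve to the lowest training-row index", {
  x <- rbind(c(1, 0), c(-1, 0), c(0, 2))
  m <- knn_fit(x, c("first", "second", "far"), k = 1)
  expect_identical(predict(m, c(0, 0)), "first")
})

test_that("Mahalanobis and Minkowski metrics match their direct-formula oracles", {
  set.seed(53)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- sample(0:1, 60, replace = TRUE)
  q <- matrix(rnorm(15), 5, 3)
  # minkowski p = 3
  m3 <- knn_fit(x, y, k = 1, metric = "minkowski", p = 3)
  oracle3 <- apply(q, 1, function(v) y[which.min(rowSums(abs(sweep(x, 2, v))^3))])
  expect_equal(predict(m3, q), oracle3)
  # mahalanobis (same ridge as the implementation)
  cv <- cov(x); diag(cv) <- diag(cv) + 1e-8 * mean(diag(cv))
  mm <- knn_fit(x, y, k = 1, metric = "mahalanobis")
  oracleM <- apply(q, 1, function(v) y[which.min(stats::mahalanobis(x, v, cv))])
  expect_equal(predict(mm, q), oracleM)
})

test_that("classifier fitting validates its state and inputs", {
  expect_fbewt_error(knn_fit(matrix(numeric(0), 0, 2), character(0)),
                     "fbewt_invalid_state")
  expect_fbewt_error(knn_fit(matrix(1:4, 2), c("a", "b", "c")),
                     "fbewt_invalid_argument")
  expect_fbewt_error(knn_fit(matrix(1:4, 2), c("a", "b"), k = 5),
                     "fbewt_invalid_argument")
  m <- knn_fit(matrix(1:4, 2), c("a", "b"))
  expect_fbewt_error(predict(m, c(1, 2, 3)), "fbewt_invalid_argument")
  expect_fbewt_error(classifier_spec(k = 0), "fbewt_invalid_argument")
})

test_that("both classifiers separate Gaussian blobs behind the uniform interface", {
  set.seed(54)
  x <- rbind(matrix(rnorm(120, 0), 60, 2), matrix(rnorm(120, 4), 60, 2))
  y <- rep(c(0, 1), each = 60)
  q <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
  truth <- rep(c(0, 1), each = 20)
  for (cl in c("knn", "svm_cubic")) {
    fit <- fit_classifier(classifier_spec(cl), x, y)
    pred <- predict(fit, q)
    expect_true(is.numeric(pred))
    expect_gt(mean(pred == truth), 0.9)
  }
  # standardisation makes a deliberately mis-scaled copy behave like the original
  x2 <- cbind(x[, 1] * 1e6, x[, 2])
  q2 <- cbind(q[, 1] * 1e6, q[, 2])
  p_std <- predict(fit_classifier(classifier_spec("knn"), x2, y), q2)
  p_raw <- predict(fit_classifier(classifier_spec("knn", standardize = FALSE), x2, y), q2)
  expect_gt(mean(p_std == truth), mean(p_raw == truth) - 0.05)
})
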