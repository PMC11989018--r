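# Formula-level classifiers and the delegated baseline contract.

test_that("SDC picks the zero-distance class and approaches 1-NN for large lambda", {
  tr <- blob_data(10, 3, shift = 4, seed = 1)
  probe <- tr$x[15, , drop = FALSE]          # a class-1 training sample
  expect_equal(sdc_fit_predict(tr$x, tr$y, probe), 1L)

  set.seed(2)
  test <- matrix(rnorm(50 * 3, mean = 2), 50, 3)
  p_sdc <- sdc_fit_predict(tr$x, tr$y, test, lambda = 100)
  p_1nn <- as.integer(as.character(class::knn(tr$x, test, factor(tr$y), k = 1)))
  expect_equal(p_sdc, p_1nn)

  expect_error(sdc_fit_predict(tr$x, tr$y, test, lambda = 0), "positive")
  expect_equal(formals(sdc_fit_predict)$lambda, 0.458)  # published default
})

test_that("SDC at small lambda behaves like a nearest-mean rule on symmetric classes", {
  set.seed(6)
  x <- rbind(matrix(rnorm(100, -2, 0.5), 50, 2), matrix(rnorm(100, 2, 0.5), 50, 2))
  y <- rep(c(0L, 1L), each = 50)
  test <- rbind(c(-1, -1), c(1, 1), c(-3, 0), c(0, 3))
  centroid_rule <- apply(test, 1, function(v) {
    d0 <- sum((v - colMeans(x[y == 0, ]))^2)
    d1 <- sum((v - colMeans(x[y == 1, ]))^2)
    as.integer(d1 < d0)
  })
  expect_equal(sdc_fit_predict(x, y, test, lambda = 1e-4), centroid_rule)
})

test_that("BLDC reduces to least squares without regularization", {
  set.seed(3)
  n <- 30; d <- 4
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c(0L, 1L), 15)
  m <- bldc_fit(X, y, beta = 1, alpha_reg = 0, epsilon_bias = 0)
  V <- cbind(X, 1)
  a <- ifelse(y == 0, 0.15, 0.85)
  expect_equal(m$U, drop(solve(crossprod(V), crossprod(V, a))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("BLDC shrinks with alpha and its predictive variance exceeds the noise floor", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3); y <- rep(c(0L, 1L), 10)
  norms <- sapply(c(0.01, 1, 100, 1e4), function(a) {
    sqrt(sum(bldc_fit(X, y, alpha_reg = a)$U[1:3]^2))
  })
  expect_true(all(diff(norms) < 0))           # ridge limit: weights -> 0

  m <- bldc_fit(X, y, beta = 2)
  pr <- predict(m, matrix(rnorm(30), 10, 3))
  expect_true(all(pr$var > 1 / 2))
  expect_true(all(pr$labels %in% c(0L, 1L)))
  expect_error(predict(m, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("BLDC on a 3-sample 1-feature set matches the hand-built linear system", {
  X <- matrix(c(1, 2, 4), 3, 1)
  y <- c(0L, 1L, 1L)
  m <- bldc_fit(X, y, beta = 1, alpha_reg = 1, epsilon_bias = 1)
  # by hand: V = rbind(x, 1) (2 x 3), precision = V V' + I,
  # U = precision^-1 V a with a = (0.15, 0.85, 0.85)
  a <- c(0.15, 0.85, 0.85)
  P <- matrix(c(1 + 4 + 16 + 1, 1 + 2 + 4,
                1 + 2 + 4, 3 + 1), 2, 2)
  U_hand <- solve(P, c(sum(X[, 1] * a), sum(a)))
  expect_equal(m$U, U_hand, ignore_attr = TRUE)

  pr <- predict(m, matrix(3, 1, 1))
  expect_equal(pr$mu, 3 * U_hand[1] + U_hand[2])
  H_hand <- solve(P)
  expect_equal(pr$var, 1 + c(3, 1) %*% H_hand %*% c(3, 1), ignore_attr = TRUE)
})

test_that("the MLP learns separable blobs quickly and solves XOR with enough epochs", {
  tr <- blob_data(30, 2, shift = 4, seed = 2)
  m <- mlp_train(tr$x, tr$y, hidden = 8, lr = 0.45, epochs = 15,
                 batch_size = 8, seed = 1)
  expect_gte(mean(predict(m, tr$x) == tr$y), 0.95)
  expect_length(m$loss_trace, 15)

  m0 <- mlp_train(tr$x, tr$y, epochs = 0, seed = 1)
  expect_length(m0$loss_trace, 0)
  expect_true(all(predict(m0, tr$x) %in% c(0L, 1L)))

  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  xor_y <- c(0L, 1L, 1L, 0L)
  mx <- mlp_train(xor_x, xor_y, hidden = 4, lr = 2, epochs = 3000,
                  max_epochs = 3000, seed = 3)
  expect_equal(predict(mx, xor_x), xor_y)

  expect_error(mlp_train(tr$x, tr$y, epochs = 20), "max_epochs")
})

test_that("MLP training is deterministic under a fixed seed", {
  tr <- blob_data(15, 3, shift = 2, seed = 9)
  m1 <- mlp_train(tr$x, tr$y, hidden = 5, epochs = 10, seed = 42)
  m2 <- mlp_train(tr$x, tr$y, hidden = 5, epochs = 10, seed = 42)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$W1, m2$W1)
})

test_that("MLP loss is non-increasing for a small learning rate", {
  tr <- blob_data(20, 2, shift = 2, seed = 3)
  m <- mlp_train(tr$x, tr$y, hidden = 6, lr = 0.05, epochs = 15, seed = 2)
  expect_true(all(diff(m$loss_trace) <= 1e-6))
})

test_that("baselines load published defaults and separate an easy set", {
  expect_error(make_classifier("nope"), "arg")

  # published parameter loading
  knn <- make_classifier("knn")
  expect_equal(knn$fit(matrix(0, 6, 2), rep(0:1, 3))$k, 5L)

  # three points per class, far apart on the deep-feature intensity scale
  set.seed(1)
  bx <- rbind(matrix(rnorm(6, 50, 5), 3, 2), matrix(rnorm(6, 200, 5), 3, 2))
  by <- rep(c(0L, 1L), each = 3)
  for (nm in c("svm", "dt", "rf", "knn", "sdc", "bldc", "mlp")) {
    clf <- make_classifier(nm)
    expect_equal(clf$predict(clf$fit(bx, by), bx), by, label = nm)
  }
})

test_that("deterministic classifiers are invariant to training-row permutation", {
  tr <- blob_data(15, 4, shift = 1.5, seed = 8)
  set.seed(2)
  test <- matrix(rnorm(40), 10, 4)
  perm <- sample(nrow(tr$x))
  for (nm in c("sdc", "bldc", "knn")) {
    clf <- make_classifier(nm)
    p1 <- clf$predict(clf$fit(tr$x, tr$y), test)
    p2 <- clf$predict(clf$fit(tr$x[perm, ], tr$y[perm]), test)
    expect_equal(p1, p2, label = nm)
  }
})
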