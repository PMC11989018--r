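# Stratified folds, confusion matrices (benign = positive), the metric
# suite, and the cross-validation harness.

test_that("stratified folds partition the data with balanced class counts", {
  y <- rep(c(0, 1), each = 5)
  plan <- kfold_plan(y, K = 5, seed = 1)
  expect_equal(sort(unique(plan$fold)), 1:5)
  expect_true(all(table(plan$fold) == 2))

  plan2 <- kfold_plan(y, K = 5, seed = 1)
  expect_identical(plan$fold, plan2$fold)      # same seed, same plan

  y100 <- rep(c(0, 1), each = 50)
  p10 <- kfold_plan(y100, K = 10, seed = 3)
  tab <- table(p10$fold, y100)
  expect_true(all(tab == 5))                   # 5 per class per fold

  expect_error(kfold_plan(y, K = 6, seed = 1), "smallest class")
})

test_that("confusion counts follow the benign-positive convention", {
  t5 <- rep(c(0, 1), each = 5)
  cm <- confusion(t5, t5)
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]), c(TP = 5, TN = 5, FP = 0, FN = 0))

  cm2 <- confusion(t5, rep(0, 10))             # everything called benign
  expect_equal(unlist(cm2[c("TP", "TN", "FP", "FN")]), c(TP = 5, TN = 0, FP = 5, FN = 0))

  truth <- c(0, 0, 0, 1, 1, 1, 0, 1)
  pred <- c(0, 1, 0, 1, 0, 1, 1, 0)
  cm3 <- confusion(truth, pred)
  expect_equal(cm3$TP, 2)   # benign -> benign: positions 1, 3
  expect_equal(cm3$TN, 2)   # aca -> aca: positions 4, 6
  expect_equal(cm3$FP, 2)   # aca called benign: positions 5, 8
  expect_equal(cm3$FN, 2)   # benign called aca: positions 2, 7
  expect_error(confusion(c(0, 2), c(0, 1)), "labels")
})

test_that("the metric suite reproduces hand-computed values and degenerate flags", {
  perfect <- metrics(structure(list(TP = 50, TN = 50, FP = 0, FN = 0),
                               class = "confusion_matrix"))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$jaccard, 100)

  m <- metrics(structure(list(TP = 40, TN = 45, FP = 5, FN = 10),
                         class = "confusion_matrix"))
  expect_equal(m$accuracy, 85)
  expect_equal(m$f1, 80 / 95 * 100)
  expect_equal(m$jaccard, 40 / 55 * 100)
  expect_equal(m$g_mean, sqrt(40 / 50 * 45 / 50) * 100)

  # chance-level predictions: kappa and MCC near zero
  set.seed(7)
  truth <- rep(c(0, 1), each = 500)
  pred <- sample(c(0, 1), 1000, TRUE)
  mr <- metrics(confusion(truth, pred))
  expect_lt(abs(mr$kappa), 0.1)
  expect_lt(abs(mr$mcc), 0.1)

  degen <- metrics(structure(list(TP = 0, TN = 10, FP = 0, FN = 0),
                             class = "confusion_matrix"))
  expect_equal(degen$f1, 0)
  expect_true("f1" %in% degen$flagged)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(11)
  for (i in 1:200) {
    cm <- structure(as.list(stats::setNames(sample(0:40, 4, TRUE),
                                            c("TP", "TN", "FP", "FN"))),
                    class = "confusion_matrix")
    if (cm$TP + cm$TN + cm$FP + cm$FN == 0) next
    m <- metrics(cm)
    expect_equal(m$accuracy + m$error_rate, 100)
    expect_gte(m$mcc, -1 - 1e-12); expect_lte(m$mcc, 1 + 1e-12)
    expect_gte(m$kappa, -1 - 1e-12); expect_lte(m$kappa, 1)
    # F1 equals Dice; Jaccard relates to F1 by J = F1 / (2 - F1)
    if (2 * cm$TP + cm$FP + cm$FN > 0) {
      f1 <- m$f1 / 100
      expect_equal(m$jaccard / 100, f1 / (2 - f1))
    }
    # swapping the positive class preserves accuracy and |MCC|
    sw <- metrics(structure(list(TP = cm$TN, TN = cm$TP, FP = cm$FN, FN = cm$FP),
                            class = "confusion_matrix"))
    expect_equal(sw$accuracy, m$accuracy)
    if (!length(m$flagged) && !length(sw$flagged)) {
      expect_equal(abs(sw$mcc), abs(m$mcc))
    }
  }
})

test_that("cross-validation fits fold-internal steps on training folds only", {
  lf <- blob_data(20, 3, shift = 4, seed = 1)
  plan <- kfold_plan(lf$y, K = 5, seed = 2)
  knn_pipe <- function(X, y) {
    clf <- make_classifier("knn")
    m <- clf$fit(X, y)
    function(Xt) clf$predict(m, Xt)
  }
  res <- cross_validate(knn_pipe, lf$x, lf$y, plan)
  expect_equal(res$mean[["accuracy"]], 100)     # separable case
  expect_equal(nrow(res$per_fold), 5)

  # label permutation: near-chance accuracy
  set.seed(5)
  yp <- sample(lf$y)
  resp <- cross_validate(knn_pipe, lf$x, yp, kfold_plan(yp, 5, seed = 2))
  expect_lt(resp$mean[["accuracy"]], 75)
  expect_gt(resp$mean[["accuracy"]], 25)
})

test_that("a test-fold-only oracle feature cannot leak into training", {
  # canary: a feature that perfectly encodes the label is planted in the
  # test folds only; training rows carry pure noise there. If any fitted
  # component saw test rows, accuracy would jump above chance.
  set.seed(8)
  n <- 40
  y <- rep(c(0L, 1L), each = 20)
  plan <- kfold_plan(y, K = 4, seed = 3)
  X <- matrix(rnorm(n * 5), n, 5)
  for (f in 1:4) {
    test_rows <- plan$fold == f
    X[test_rows, 5] <- y[test_rows] * 10       # oracle only where held out
    X[!test_rows, 5] <- rnorm(sum(!test_rows))
  }
  # the same matrix serves every fold, so each fold's TRAINING view of
  # column 5 is a mixture of noise and other folds' oracle values --
  # uncorrelated with the training labels; near-chance accuracy expected
  knn_pipe <- function(Xtr, ytr) {
    clf <- make_classifier("knn")
    m <- clf$fit(Xtr, ytr)
    function(Xt) clf$predict(m, Xt)
  }
  res <- cross_validate(knn_pipe, X, y, plan)
  expect_lt(res$mean[["accuracy"]], 80)
})

test_that("more folds do not systematically hurt accuracy", {
  accs <- sapply(1:4, function(s) {
    lf <- blob_data(20, 4, shift = 1.2, seed = s)
    a2 <- cross_validate(function(X, y) {
      clf <- make_classifier("knn"); m <- clf$fit(X, y)
      function(Xt) clf$predict(m, Xt)
    }, lf$x, lf$y, kfold_plan(lf$y, 2, seed = s))$mean[["accuracy"]]
    a10 <- cross_validate(function(X, y) {
      clf <- make_classifier("knn"); m <- clf$fit(X, y)
      function(Xt) clf$predict(m, Xt)
    }, lf$x, lf$y, kfold_plan(lf$y, 10, seed = s))$mean[["accuracy"]]
    c(a2, a10)
  })
  expect_gte(mean(accs[2, ]), mean(accs[1, ]) - 5)
})
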