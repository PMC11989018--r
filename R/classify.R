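# Classification layer: formula-level classifiers implemented from their
# defining equations (softmax discriminant, Bayesian linear discriminant,
# single-hidden-layer MLP) and a uniform contract wrapping the delegated
# baselines (SVM-RBF, decision tree, random forest, weighted KNN).
#
# All classifiers consume a numeric feature matrix and 0/1 labels
# (0 = benign, 1 = abnormal) and predict 0/1 labels.

#' Softmax discriminant classifier
#'
#' Assigns a test vector v to the class j maximizing
#' `log sum_n exp(-lambda * ||v - v_n^j||^2)` over that class's training
#' samples: a soft nearest-neighbor rule whose sharpness grows with the
#' penalty `lambda`. Score ties go to class 0.
#'
#' @param train_x training feature matrix.
#' @param train_y 0/1 labels (both classes present).
#' @param test_x test feature matrix.
#' @param lambda positive distance penalty (default 0.458).
#' @return integer 0/1 predictions for the rows of `test_x`.
#' @export
sdc_fit_predict <- function(train_x, train_y, test_x, lambda = 0.458) {
  if (lambda <= 0) stop("lambda must be positive")
  train_y <- .check_labels(train_y, nrow(train_x))
  score_class <- function(v, cls) {
    rows <- train_x[train_y == cls, , drop = FALSE]
    d2 <- rowSums((rows - matrix(v, nrow(rows), length(v), byrow = TRUE))^2)
    logsumexp(-lambda * d2)
  }
  apply(test_x, 1, function(v) {
    s0 <- score_class(v, 0L); s1 <- score_class(v, 1L)
    if (s1 > s0) 1L else 0L        # tie -> class 0
  })
}

#' Fit a Bayesian linear discriminant classifier
#'
#' Ridge-regularized Bayesian linear regression of class targets on the
#' bias-augmented features. With V the (d+1) x n matrix of augmented
#' training vectors and a the target vector, the Gaussian posterior over
#' the weights has covariance `H = (beta V V' + R(alpha))^{-1}` and mean
#' `U = beta H V a`, where `R(alpha) = diag(alpha, ..., alpha, epsilon)`
#' regularizes the feature weights by `alpha` and the bias by `epsilon`.
#' Solved by a numerically stable `solve()` of the posterior precision.
#'
#' @param train_x training feature matrix.
#' @param train_y 0/1 labels.
#' @param beta inverse noise variance (> 0).
#' @param alpha_reg weight regularizer (>= 0).
#' @param epsilon_bias bias regularizer (>= 0).
#' @param targets regression targets for classes 0 and 1 (default
#'   c(0.15, 0.85)).
#' @return a `bldc_model` with `U` (posterior mean), `H` (posterior
#'   covariance), `beta`, `targets`.
#' @export
bldc_fit <- function(train_x, train_y, beta = 1, alpha_reg = 1,
                     epsilon_bias = 1e-6, targets = c(0.15, 0.85)) {
  if (beta <= 0) stop("beta must be positive")
  train_y <- .check_labels(train_y, nrow(train_x))
  V <- rbind(t(train_x), bias = 1)                    # (d+1) x n
  a <- ifelse(train_y == 0L, targets[1], targets[2])
  R <- diag(c(rep(alpha_reg, nrow(V) - 1L), epsilon_bias), nrow(V))
  precision <- beta * tcrossprod(V) + R
  H <- tryCatch(solve(precision), error = function(e) {
    stop("singular posterior precision; increase alpha_reg (> 0) for ",
         "rank-deficient data")
  })
  U <- beta * H %*% (V %*% a)
  structure(list(U = drop(U), H = H, beta = beta, targets = targets),
            class = "bldc_model")
}

#' Predict with a Bayesian linear discriminant classifier
#'
#' The predictive distribution for an augmented test vector v is Gaussian
#' with mean `mu = v' U` and variance `delta^2 = 1/beta + v' H v`; the
#' predicted class is abnormal (1) when `mu` exceeds the target midpoint
#' (ties go to the benign class).
#'
#' @param object a `bldc_model`.
#' @param newdata test feature matrix.
#' @param ... unused.
#' @return list with `labels` (0/1), `mu`, `var`.
#' @export
predict.bldc_model <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$U) - 1L) {
    stop("feature dimension mismatch: model expects ", length(object$U) - 1L)
  }
  Vt <- cbind(newdata, 1)                             # n x (d+1)
  mu <- drop(Vt %*% object$U)
  var <- 1 / object$beta + rowSums((Vt %*% object$H) * Vt)
  thr <- mean(object$targets)
  list(labels = as.integer(mu > thr), mu = mu, var = var)
}

#' Train a single-hidden-layer MLP
#'
#' Sigmoid activations in both the hidden and output layer, squared-error
#' cost `F = 1/2 sum (target - output)^2`, minimized by (mini-)batch
#' gradient descent. Deterministic for a fixed seed. Inputs are
#' standardized internally (train-set statistics).
#'
#' @param train_x training feature matrix.
#' @param train_y 0/1 labels.
#' @param hidden hidden-layer size (default 20).
#' @param lr learning rate (default 0.45).
#' @param epochs training epochs; must not exceed `max_epochs`.
#' @param max_epochs configurable epoch cap (default 15, the published
#'   training budget; raise it for tasks that need longer training).
#' @param batch_size mini-batch size (default: full batch).
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return an `mlp_model` with weights, scaling, and `loss_trace` (summed
#'   squared-error cost per epoch; empty when `epochs = 0`).
#' @export
mlp_train <- function(train_x, train_y, hidden = 20L, lr = 0.45,
                      epochs = 15L, max_epochs = 15L, batch_size = NULL,
                      seed = 1L) {
  if (hidden < 1L) stop("hidden size must be >= 1")
  if (epochs > max_epochs) {
    stop("epochs (", epochs, ") exceeds max_epochs (", max_epochs, ")")
  }
  train_y <- .check_labels(train_y, nrow(train_x))
  n <- nrow(train_x); d <- ncol(train_x)
  ctr <- colMeans(train_x)
  scl <- apply(train_x, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
  X <- sweep(sweep(train_x, 2, ctr), 2, scl, "/")
  y <- as.numeric(train_y)
  if (is.null(batch_size)) batch_size <- n
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden)
    b1 <- rep(0, hidden)
    W2 <- stats::rnorm(hidden, sd = 1 / sqrt(hidden))
    b2 <- 0
    loss_trace <- numeric(0)
    if (epochs > 0L) for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        Xb <- X[bi, , drop = FALSE]; yb <- y[bi]
        h <- sigmoid(sweep(Xb %*% W1, 2, b1, "+"))
        out <- sigmoid(drop(h %*% W2) + b2)
        err <- out - yb                               # d cost / d out
        g_out <- err * out * (1 - out)
        gW2 <- drop(crossprod(h, g_out))
        gb2 <- sum(g_out)
        g_h <- outer(g_out, W2) * h * (1 - h)
        gW1 <- crossprod(Xb, g_h)
        gb1 <- colSums(g_h)
        W2 <- W2 - lr * gW2 / length(bi)
        b2 <- b2 - lr * gb2 / length(bi)
        W1 <- W1 - lr * gW1 / length(bi)
        b1 <- b1 - lr * gb1 / length(bi)
      }
      h <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
      out <- sigmoid(drop(h %*% W2) + b2)
      loss <- 0.5 * sum((y - out)^2)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss); lower the learning rate")
      }
      loss_trace <- c(loss_trace, loss)
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = ctr,
                   scale = scl, loss_trace = loss_trace),
              class = "mlp_model")
  })
}

#' Predict with a trained MLP
#'
#' @param object an `mlp_model`.
#' @param newdata test feature matrix.
#' @param ... unused.
#' @return integer 0/1 predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  h <- sigmoid(sweep(X %*% object$W1, 2, object$b1, "+"))
  out <- sigmoid(drop(h %*% object$W2) + object$b2)
  as.integer(out > 0.5)
}

# Distance-weighted KNN (weights 1 / (d + eps)); no installed package
# provides the weighted variant, so it is computed directly. Inputs are
# standardized by the training statistics before distances are taken.
.weighted_knn <- function(train_x, train_y, test_x, k = 5L, eps = 1e-8) {
  ctr <- colMeans(train_x)
  scl <- apply(train_x, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
  train_x <- sweep(sweep(train_x, 2, ctr), 2, scl, "/")
  test_x <- sweep(sweep(test_x, 2, ctr), 2, scl, "/")
  k <- min(k, nrow(train_x))
  apply(test_x, 1, function(v) {
    d <- sqrt(rowSums((train_x - matrix(v, nrow(train_x), length(v), byrow = TRUE))^2))
    nb <- order(d)[seq_len(k)]
    w <- 1 / (d[nb] + eps)
    s1 <- sum(w[train_y[nb] == 1L]); s0 <- sum(w[train_y[nb] == 0L])
    if (s1 > s0) 1L else 0L
  })
}

#' Uniform classifier contract
#'
#' Returns a named list with `fit(x, y) -> model` and
#' `predict(model, x) -> 0/1 labels` closures for any of the seven
#' classifiers. Baselines are delegated with their published defaults:
#' SVM with RBF kernel (kernel width sigma = 98 mapped to
#' `gamma = 1/(2 sigma^2)`, coefficient 1.8 mapped to `cost`), weighted
#' KNN (k = 5, Euclidean, inverse-distance weights), random forest
#' (150 trees, depth 15), decision tree (depth 14, entropy splits).
#'
#' @param name one of `"svm"`, `"dt"`, `"rf"`, `"knn"`, `"sdc"`, `"bldc"`,
#'   `"mlp"`.
#' @param ... overrides passed to the underlying fit function.
#' @return a `classifier_spec` list with `name`, `fit`, `predict`.
#' @export
make_classifier <- function(name = c("knn", "svm", "dt", "rf", "sdc", "bldc", "mlp"),
                            ...) {
  name <- match.arg(name)
  dots <- list(...)
  arg <- function(key, default) if (key %in% names(dots)) dots[[key]] else default
  spec <- switch(name,
    svm = list(
      fit = function(x, y) e1071::svm(
        x, factor(y, levels = c(0, 1)), kernel = "radial",
        gamma = arg("gamma", 1 / (2 * 98^2)), cost = arg("cost", 1.8),
        scale = FALSE),
      predict = function(m, x) as.integer(as.character(predict(m, x)))
    ),
    dt = list(
      fit = function(x, y) {
        df <- data.frame(y = factor(y, levels = c(0, 1)), x)
        rpart::rpart(y ~ ., data = df, method = "class",
                     parms = list(split = "information"),
                     control = rpart::rpart.control(
                       maxdepth = arg("maxdepth", 14L), minsplit = 4L, cp = 0))
      },
      predict = function(m, x) {
        as.integer(as.character(predict(m, data.frame(x), type = "class")))
      }
    ),
    rf = list(
      fit = function(x, y) {
        df <- data.frame(y = factor(y, levels = c(0, 1)), x)
        ranger::ranger(y ~ ., data = df,
                       num.trees = arg("num_trees", 150L),
                       max.depth = arg("max_depth", 15L),
                       seed = arg("seed", 1L), num.threads = 1L)
      },
      predict = function(m, x) {
        as.integer(as.character(predict(m, data.frame(x),
                                        num.threads = 1L)$predictions))
      }
    ),
    knn = list(
      fit = function(x, y) list(x = x, y = y, k = arg("k", 5L)),
      predict = function(m, x) .weighted_knn(m$x, m$y, x, k = m$k)
    ),
    sdc = list(
      fit = function(x, y) list(x = x, y = y, lambda = arg("lambda", 0.458)),
      predict = function(m, x) sdc_fit_predict(m$x, m$y, x, lambda = m$lambda)
    ),
    bldc = list(
      fit = function(x, y) bldc_fit(x, y, beta = arg("beta", 1),
                                    alpha_reg = arg("alpha_reg", 1),
                                    epsilon_bias = arg("epsilon_bias", 1e-6),
                                    targets = arg("targets", c(0.15, 0.85))),
      predict = function(m, x) predict(m, x)$labels
    ),
    mlp = list(
      fit = function(x, y) mlp_train(x, y, hidden = arg("hidden", 20L),
                                     lr = arg("lr", 0.45),
                                     epochs = arg("epochs", 15L),
                                     max_epochs = arg("max_epochs", 15L),
                                     batch_size = arg("batch_size", NULL),
                                     seed = arg("seed", 1L)),
      predict = function(m, x) predict(m, x)
    )
  )
  structure(list(name = name, fit = spec$fit, predict = spec$predict),
            class = "classifier_spec")
}
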