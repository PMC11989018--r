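# Stratified K-fold cross-validation, confusion matrices under the
# clinical positive-class convention (benign = positive), and the full
# metric suite: accuracy, error rate, F1, MCC, Jaccard, G-mean, kappa.

#' Stratified K-fold plan
#'
#' Samples of each class are shuffled (seed-controlled) and dealt
#' round-robin into K folds, so folds partition the data, per-class counts
#' differ by at most one across folds, and the plan is reproducible.
#'
#' @param labels class vector (any two-valued coding).
#' @param K number of folds; at most the size of the smallest class.
#' @param seed integer seed for the shuffle.
#' @return a `cv_plan` object with `K`, `fold` (per-sample fold index
#'   1..K) and `seed`.
#' @export
kfold_plan <- function(labels, K, seed = 1L) {
  n <- length(labels)
  if (K < 2L) stop("K must be at least 2")
  if (K > min(table(labels))) {
    stop("K (", K, ") exceeds the smallest class count (", min(table(labels)), ")")
  }
  fold <- integer(n)
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(K), length(idx))
    }
  })
  structure(list(K = as.integer(K), fold = fold, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Confusion matrix with the benign-positive convention
#'
#' The positive class is benign (label 0): TP counts benign samples
#' predicted benign, TN abnormal predicted abnormal, FP abnormal predicted
#' benign, FN benign predicted abnormal.
#'
#' @param truth,predicted equal-length 0/1 vectors (0 = benign, 1 = abnormal).
#' @return a `confusion_matrix` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("vectors must have equal length")
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (!all(c(truth, predicted) %in% c(0L, 1L))) {
    stop("labels must be 0 (benign) or 1 (abnormal)")
  }
  structure(list(
    TP = sum(truth == 0L & predicted == 0L),
    TN = sum(truth == 1L & predicted == 1L),
    FP = sum(truth == 1L & predicted == 0L),
    FN = sum(truth == 0L & predicted == 1L)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (positive = benign):\n")
  cat(sprintf("  TP = %d  FN = %d\n  FP = %d  TN = %d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

# Safe ratio: 0 with a flag when the denominator vanishes.
.safe_div <- function(num, den) {
  if (den == 0) list(value = 0, flagged = TRUE) else list(value = num / den, flagged = FALSE)
}

#' Classification metric suite from a confusion matrix
#'
#' Accuracy, error rate, F1 (= Dice), Jaccard and G-mean are reported as
#' percentages; MCC and Cohen's kappa on \[-1, 1\]. Kappa uses the chance
#' agreement Pr(e) from the marginal products. Any metric with an undefined
#' (zero) denominator is reported as 0 and listed in `flagged`.
#'
#' @param cm a [confusion()] result.
#' @return a `metric_set` list: `accuracy`, `error_rate`, `f1`, `mcc`,
#'   `jaccard`, `g_mean`, `kappa`, `flagged` (character vector).
#' @export
metrics <- function(cm) {
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion matrix")
  flagged <- character(0)
  note <- function(res, name) {
    if (res$flagged) flagged <<- c(flagged, name)
    res$value
  }
  accuracy <- (TP + TN) / total * 100
  error_rate <- (FP + FN) / total * 100
  f1 <- note(.safe_div(2 * TP, 2 * TP + FP + FN), "f1") * 100
  jaccard <- note(.safe_div(TP, TP + FP + FN), "jaccard") * 100
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- note(.safe_div(as.numeric(TN) * TP - as.numeric(FN) * FP, mcc_den), "mcc")
  sens <- note(.safe_div(TP, TP + FN), "sensitivity")
  spec <- note(.safe_div(TN, TN + FP), "specificity")
  g_mean <- sqrt(sens * spec) * 100
  pr_a <- (TP + TN) / total
  pr_e <- ((TP + FP) * (TP + FN) + (TN + FP) * (TN + FN)) / total^2
  kappa <- note(.safe_div(pr_a - pr_e, 1 - pr_e), "kappa")
  structure(list(accuracy = accuracy, error_rate = error_rate, f1 = f1,
                 mcc = mcc, jaccard = jaccard, g_mean = g_mean, kappa = kappa,
                 flagged = unique(flagged)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  error %.2f%%  F1 %.2f%%  Jaccard %.2f%%  G-mean %.2f%%\n",
              x$accuracy, x$error_rate, x$f1, x$jaccard, x$g_mean))
  cat(sprintf("MCC %.4f  kappa %.4f", x$mcc, x$kappa))
  if (length(x$flagged)) cat("  [flagged: ", paste(x$flagged, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# Subset features that may be a matrix or a list of conformable matrices.
.subset_features <- function(features, rows) {
  if (is.list(features)) lapply(features, function(m) m[rows, , drop = FALSE])
  else features[rows, , drop = FALSE]
}

#' Cross-validate a pipeline
#'
#' For each fold, `pipeline(features_train, labels_train)` is called to fit
#' every fold-internal step (fusion offsets, feature selection, the
#' classifier itself) on the training folds only; the returned predictor
#' `function(features_test) -> 0/1 labels` is applied to the held-out fold.
#' Per-fold metrics and their mean and standard deviation are returned.
#'
#' @param pipeline function(features, labels) -> function(features) -> labels.
#' @param features feature matrix or list of conformable matrices (for
#'   pipelines consuming a backbone triplet).
#' @param labels 0/1 vector.
#' @param plan a [kfold_plan()].
#' @return a `cv_result` list: `per_fold` (data.frame of fold metrics),
#'   `mean`, `sd` (named numeric vectors).
#' @export
cross_validate <- function(pipeline, features, labels, plan) {
  n <- length(labels)
  if (length(plan$fold) != n) stop("plan does not match the data")
  metric_names <- c("accuracy", "error_rate", "f1", "mcc", "jaccard", "g_mean", "kappa")
  rows <- lapply(seq_len(plan$K), function(f) {
    tr <- plan$fold != f
    if (length(unique(labels[tr])) < 2L) {
      stop("training folds for fold ", f, " contain a single class")
    }
    predictor <- pipeline(.subset_features(features, tr), labels[tr])
    pred <- predictor(.subset_features(features, !tr))
    m <- metrics(confusion(labels[!tr], pred))
    as.data.frame(c(list(fold = f), m[metric_names]))
  })
  per_fold <- do.call(rbind, rows)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_names]),
    sd = apply(per_fold[metric_names], 2, stats::sd)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation over", nrow(x$per_fold), "folds\n")
  cat(sprintf("  mean accuracy %.2f%% (sd %.2f)\n",
              x$mean[["accuracy"]], x$sd[["accuracy"]]))
  cat(sprintf("  mean F1 %.2f%%  mean MCC %.4f\n",
              x$mean[["f1"]], x$mean[["mcc"]]))
  invisible(x)
}
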