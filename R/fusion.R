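# Deep-weighted averaging feature fusion (DWAFF): simplex-weighted
# combination of three backbone feature matrices with optional per-class
# mean offsets, plus the weight search and feature diagnostics.
#
# Throughout, labels are 0 = normal/benign and 1 = abnormal/ACA, and the
# weight order is w1 -> deepest backbone (f152), w2 -> f101, w3 -> f50.

#' Fusion weights on the probability simplex
#'
#' @param w1,w2,w3 non-negative weights summing to 1 (w1 weighs the deepest
#'   backbone).
#' @return a `fusion_weights` object.
#' @export
fusion_weights <- function(w1, w2, w3) {
  w <- c(w1 = w1, w2 = w2, w3 = w3)
  if (any(w < -1e-12) || any(w > 1 + 1e-12)) stop("weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  structure(as.list(pmin(pmax(w, 0), 1)), class = "fusion_weights")
}

.check_triplet <- function(f50, f101, f152) {
  d <- dim(f50)
  if (!identical(d, dim(f101)) || !identical(d, dim(f152))) {
    stop("backbone feature matrices must have identical dimensions")
  }
  if (anyNA(f50) || anyNA(f101) || anyNA(f152) ||
      !all(is.finite(f50), is.finite(f101), is.finite(f152))) {
    stop("feature matrices must be finite")
  }
  invisible(d)
}

.check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) stop("label count must equal row count")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 (normal) or 1 (abnormal)")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  labels
}

#' Extract features from a list of images
#'
#' Adapter around any user-supplied feature extractor: a function mapping
#' one image to a fixed-length numeric vector. Rows follow the input order.
#'
#' @param images list of images.
#' @param extractor function(image) -> numeric vector.
#' @return numeric matrix with one row per image.
#' @export
extract_features <- function(images, extractor) {
  rows <- lapply(images, function(im) {
    v <- extractor(im)
    if (!is.numeric(v)) stop("extractor must return a numeric vector")
    v
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("extractor contract violation: inconsistent vector lengths (",
         paste(unique(lens), collapse = ", "), ")")
  }
  do.call(rbind, rows)
}

#' Per-class mean offsets across backbones
#'
#' For each class, the grand mean of all feature entries in that class's
#' rows is taken per backbone, and the three backbone values are averaged.
#'
#' @param f50,f101,f152 conformable feature matrices.
#' @param labels 0/1 class vector (both classes present).
#' @return list with `mean_normal` and `mean_abnormal`.
#' @export
class_mean_offsets <- function(f50, f101, f152, labels) {
  .check_triplet(f50, f101, f152)
  labels <- .check_labels(labels, nrow(f50))
  per_class <- function(cls) {
    rows <- labels == cls
    mean(c(mean(f50[rows, , drop = FALSE]),
           mean(f101[rows, , drop = FALSE]),
           mean(f152[rows, , drop = FALSE])))
  }
  list(mean_normal = per_class(0L), mean_abnormal = per_class(1L))
}

#' DWAFF feature fusion
#'
#' `faithful` mode reproduces the published construction: the weighted sum
#' `w1 * f152 + w2 * f101 + w3 * f50` is divided by 3 (as printed in the
#' per-class fusion equations; drop via `divide_by_three = FALSE`) and the
#' class mean (normal or abnormal) is added to each row according to its
#' label. Adding the class mean uses the labels, so faithful mode is for
#' training data only — during cross-validation the offsets must be
#' estimated on training folds. `leak_free` mode is the plain convex
#' combination with no offset and no divisor, usable on unlabeled data.
#'
#' @param f50,f101,f152 conformable feature matrices.
#' @param w a [fusion_weights()].
#' @param labels 0/1 vector (required in faithful mode).
#' @param means list from [class_mean_offsets()] (required in faithful mode).
#' @param mode `"leak_free"` (default) or `"faithful"`.
#' @param divide_by_three apply the printed /3 divisor in faithful mode.
#' @return fused feature matrix of the same dimensions.
#' @export
dwaff_fuse <- function(f50, f101, f152, w, labels = NULL, means = NULL,
                       mode = c("leak_free", "faithful"), divide_by_three = TRUE) {
  mode <- match.arg(mode)
  .check_triplet(f50, f101, f152)
  fused <- w$w1 * f152 + w$w2 * f101 + w$w3 * f50
  if (mode == "leak_free") return(fused)
  if (is.null(labels) || is.null(means)) {
    stop("faithful mode needs labels and class means")
  }
  labels <- .check_labels(labels, nrow(f50))
  if (divide_by_three) fused <- fused / 3
  offset <- ifelse(labels == 0L, means$mean_normal, means$mean_abnormal)
  fused + offset
}

# Mean K-fold accuracy of an unweighted KNN (k = 5) reference classifier;
# the deterministic score used by the fusion-weight search and the wrapper
# fitness. Features are standardized with training-fold statistics so no
# coordinate dominates the Euclidean distance by scale alone.
.knn_cv_score <- function(X, labels, folds, k = 5L) {
  acc <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    std <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
    pred <- class::knn(std(X[tr, , drop = FALSE]), std(X[!tr, , drop = FALSE]),
                       factor(labels[tr]), k = min(k, sum(tr)), use.all = TRUE)
    mean(pred == factor(labels[!tr]))
  }, numeric(1))
  mean(acc)
}

#' Grid search for fusion weights
#'
#' Enumerates every weight triple on the simplex grid of step `grid_step`,
#' fuses the three backbones (leak-free mode) under each triple, scores it
#' by the mean stratified K-fold accuracy of a KNN (k = 5) reference
#' classifier averaged over the requested K values, and returns the best.
#' Score ties are broken toward larger `w1` (the deepest backbone), then
#' larger `w2`.
#'
#' @param f50,f101,f152 conformable feature matrices.
#' @param labels 0/1 vector.
#' @param K_values fold counts to average over (subset of 2, 4, 5, 8, 10).
#' @param grid_step simplex grid step (0.05 or 0.1).
#' @param seed seed controlling the fold shuffles.
#' @return list with `weights` (a [fusion_weights()]) and `table`
#'   (data.frame of all scored triples).
#' @export
search_fusion_weights <- function(f50, f101, f152, labels, K_values = c(5L),
                                  grid_step = 0.05, seed = 1L) {
  if (!grid_step %in% c(0.05, 0.1)) stop("grid_step must be 0.05 or 0.1")
  if (!all(K_values %in% c(2L, 4L, 5L, 8L, 10L))) {
    stop("K_values must be a subset of {2, 4, 5, 8, 10}")
  }
  .check_triplet(f50, f101, f152)
  labels <- .check_labels(labels, nrow(f50))
  steps <- round(1 / grid_step)
  grid <- expand.grid(i = 0:steps, j = 0:steps)
  grid <- grid[grid$i + grid$j <= steps, ]
  w1 <- grid$i * grid_step; w2 <- grid$j * grid_step; w3 <- 1 - w1 - w2
  if (nrow(grid) == 0L) stop("empty weight grid")
  fold_sets <- lapply(K_values, function(K) {
    kfold_plan(labels, K = K, seed = seed + K)$fold
  })
  score <- vapply(seq_along(w1), function(g) {
    fused <- w1[g] * f152 + w2[g] * f101 + w3[g] * f50
    mean(vapply(fold_sets, function(fd) .knn_cv_score(fused, labels, fd), numeric(1)))
  }, numeric(1))
  tab <- data.frame(w1 = w1, w2 = w2, w3 = w3, score = score)
  ord <- order(-tab$score, -tab$w1, -tab$w2)
  best <- tab[ord[1], ]
  list(weights = fusion_weights(best$w1, best$w2, best$w3), table = tab)
}

#' Per-class feature statistics
#'
#' For each class: grand mean, sample variance, moment skewness and moment
#' kurtosis (Gaussian reference 3) of all feature entries. Across classes:
#' the Pearson correlation between the per-image feature-mean vectors of
#' the two classes (truncated to equal length) and the Dice coefficient of
#' the classes' binarized (per-feature mean above the grand mean) masks.
#' A zero-variance class reports skewness and kurtosis of 0 with
#' `degenerate = TRUE`.
#'
#' @param f feature matrix.
#' @param labels 0/1 vector with at least 2 rows per class.
#' @return list with per-class stats (`normal`, `abnormal`), `pcc`, `dice`.
#' @export
feature_statistics <- function(f, labels) {
  labels <- .check_labels(labels, nrow(f))
  if (min(table(labels)) < 2L) stop("need at least 2 rows per class")
  one_class <- function(cls) {
    x <- as.vector(f[labels == cls, , drop = FALSE])
    v <- stats::var(x)
    degenerate <- !is.finite(v) || v < 1e-24
    list(mean = mean(x), variance = v,
         skewness = if (degenerate) 0 else e1071::skewness(x, type = 1),
         kurtosis = if (degenerate) 0 else e1071::kurtosis(x, type = 1) + 3,
         degenerate = degenerate)
  }
  n_means <- rowMeans(f[labels == 0L, , drop = FALSE])
  a_means <- rowMeans(f[labels == 1L, , drop = FALSE])
  len <- min(length(n_means), length(a_means))
  nm <- n_means[seq_len(len)]; am <- a_means[seq_len(len)]
  pcc <- if (stats::sd(nm) == 0 || stats::sd(am) == 0) {
    # degenerate: correlation undefined; identical vectors count as 1
    if (isTRUE(all.equal(nm, am))) 1 else 0
  } else {
    stats::cor(nm, am)
  }
  grand <- mean(f)
  mask_n <- colMeans(f[labels == 0L, , drop = FALSE]) > grand
  mask_a <- colMeans(f[labels == 1L, , drop = FALSE]) > grand
  denom <- sum(mask_n) + sum(mask_a)
  dice <- if (denom == 0) 1 else 2 * sum(mask_n & mask_a) / denom
  list(normal = one_class(0L), abnormal = one_class(1L), pcc = pcc, dice = dice)
}
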