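# Modified SLIC superpixel clustering on the (x, y, grayscale) feature
# space: grid seeding with gradient-aware perturbation, circular-window
# assignment, Lloyd-style center updates, and small-segment merging.
#
# Coordinates are 0-based: x = column, y = row. Cluster centers carry
# (x, y, gs) with gs the grayscale value of the (enhanced) image.

#' SLIC configuration
#'
#' @param M target superpixel count (>= 4).
#' @param compactness compactness factor m in \[1, 40\]; larger m favors
#'   spatially regular superpixels over intensity adherence.
#' @param k_thresholds number of entropy thresholds for the enhancement
#'   stage (1..4).
#' @param r_power exponent of the enhancement curves (>= 1).
#' @param max_iter maximum clustering iterations.
#' @param conv_tol convergence tolerance: mean center displacement in pixels.
#' @param min_size_frac minimum segment size as a fraction of S^2 (the
#'   nominal superpixel area); segments below `floor(min_size_frac * S^2)`
#'   pixels are merged away.
#' @param alpha optional override of the grayscale weight in the distance
#'   `d'^2 = d_spatial^2 + alpha * d_gray^2`; the default `(S / m)^2` makes
#'   the grayscale and spatial terms commensurate as in standard SLIC.
#' @param enhance apply entropy-guided contrast enhancement before
#'   clustering (TRUE by default; the modified pipeline's Step 02).
#' @return a `slic_config` list.
#' @export
slic_config <- function(M = 64L, compactness = 20, k_thresholds = 2L,
                        r_power = 2, max_iter = 10L, conv_tol = 0.5,
                        min_size_frac = 0.25, alpha = NULL, enhance = TRUE) {
  if (M < 4L) stop("M must be at least 4")
  if (compactness < 1 || compactness > 40) stop("compactness must lie in [1, 40]")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(M = as.integer(M), compactness = compactness,
                 k_thresholds = as.integer(k_thresholds), r_power = r_power,
                 max_iter = as.integer(max_iter), conv_tol = conv_tol,
                 min_size_frac = min_size_frac, alpha = alpha,
                 enhance = isTRUE(enhance)),
            class = "slic_config")
}

#' Initialize cluster centers on a regular grid
#'
#' Centers are spaced `S = sqrt(N / M)` apart (so each superpixel nominally
#' holds N / M pixels), then each is moved to the minimum-gradient position
#' in its 3 x 3 neighborhood (ties keep the grid position; gradient is the
#' squared central-difference magnitude with reflecting borders).
#'
#' @param img grayscale matrix (typically the enhanced image).
#' @param M target superpixel count; must satisfy `M <= N / 4`.
#' @return data.frame with columns `x`, `y` (0-based, integer), `gs`,
#'   `label` (0-based).
#' @export
grid_init_centers <- function(img, M) {
  assert_gray_image(img)
  H <- nrow(img); W <- ncol(img); N <- H * W
  if (M > N / 4) stop("M too large: at most N/4 superpixels supported")
  S <- sqrt(N / M)
  nx <- max(1L, as.integer(round(W / S)))
  ny <- max(1L, as.integer(round(H / S)))
  cx <- round((seq_len(nx) - 0.5) * W / nx - 0.5)   # 0-based columns
  cy <- round((seq_len(ny) - 0.5) * H / ny - 0.5)
  grid <- expand.grid(y = cy, x = cx)
  g <- .gradient_magnitude(img)
  pos <- t(mapply(function(y, x) .min_gradient_shift(g, y, x), grid$y, grid$x))
  data.frame(
    x = pos[, 2], y = pos[, 1],
    gs = img[cbind(pos[, 1] + 1L, pos[, 2] + 1L)],
    label = seq_len(nrow(grid)) - 1L
  )
}

.gradient_magnitude <- function(img) {
  H <- nrow(img); W <- ncol(img)
  up <- img[reflect_index(H, 1L)[seq_len(H)], , drop = FALSE]
  down <- img[reflect_index(H, 1L)[seq_len(H) + 2L], , drop = FALSE]
  left <- img[, reflect_index(W, 1L)[seq_len(W)], drop = FALSE]
  right <- img[, reflect_index(W, 1L)[seq_len(W) + 2L], drop = FALSE]
  ((down - up) / 2)^2 + ((right - left) / 2)^2
}

.min_gradient_shift <- function(g, y, x) {
  H <- nrow(g); W <- ncol(g)
  ys <- pmin(pmax((y - 1L):(y + 1L), 0L), H - 1L)
  xs <- pmin(pmax((x - 1L):(x + 1L), 0L), W - 1L)
  cand <- expand.grid(y = unique(ys), x = unique(xs))
  vals <- g[cbind(cand$y + 1L, cand$x + 1L)]
  center_val <- g[y + 1L, x + 1L]
  if (min(vals) >= center_val) return(c(y, x))   # ties keep the grid position
  j <- which.min(vals)
  c(cand$y[j], cand$x[j])
}

#' Grayscale-spatial distance between a pixel and a cluster center
#'
#' `d' = sqrt(d_ss^2 + alpha * d_gs^2)` with `d_ss` the Euclidean spatial
#' distance and `d_gs` the absolute grayscale difference.
#'
#' @param center list/row with `x`, `y`, `gs`.
#' @param px_x,px_y pixel coordinates (0-based).
#' @param g pixel grayscale value.
#' @param alpha grayscale weight (> 0).
#' @return the combined distance.
#' @export
pixel_distance <- function(center, px_x, px_y, g, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  sqrt((center$x - px_x)^2 + (center$y - px_y)^2 + alpha * (center$gs - g)^2)
}

#' Iterative SLIC clustering
#'
#' Repeats: for each center, pixels within Euclidean spatial radius S
#' (a circular window) compete for assignment by the combined distance
#' `d'^2 = d_spatial^2 + alpha * d_gray^2`; each pixel takes the minimizing
#' center (distance ties go to the lower label, and a pixel's current
#' center always remains a candidate, so the summed squared distance never
#' increases); then every center moves to the mean (x, y, gs) of its
#' pixels. Stops when the mean center displacement drops below
#' `conv_tol` or after `max_iter` iterations. Pixels not covered by any
#' circular window (possible at image corners) are assigned to the nearest
#' center by `d'`.
#'
#' @param img grayscale matrix.
#' @param centers data.frame from [grid_init_centers()].
#' @param cfg a [slic_config()].
#' @return list with `labels` (H x W integer matrix, 0-based labels),
#'   `centers`, `cost_trace` (summed squared `d'` after each assignment),
#'   `iterations`, and `converged`.
#' @export
slic_iterate <- function(img, centers, cfg) {
  assert_gray_image(img)
  H <- nrow(img); W <- ncol(img); N <- H * W
  S <- sqrt(N / nrow(centers))
  alpha <- if (is.null(cfg$alpha)) (S / cfg$compactness)^2 else cfg$alpha
  px_y <- matrix(rep(0:(H - 1L), W), H, W)     # row coordinate y
  px_x <- matrix(rep(0:(W - 1L), each = H), H, W)
  labels <- matrix(NA_integer_, H, W)
  cost_trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg$max_iter)) {
    iters <- it
    best <- matrix(Inf, H, W)
    new_labels <- matrix(NA_integer_, H, W)
    for (ci in seq_len(nrow(centers))) {
      cx <- centers$x[ci]; cy <- centers$y[ci]; cg <- centers$gs[ci]
      rs <- max(0L, floor(cy - S)):min(H - 1L, ceiling(cy + S))
      cs <- max(0L, floor(cx - S)):min(W - 1L, ceiling(cx + S))
      ri <- rs + 1L; cj <- cs + 1L
      dy2 <- (rs - cy)^2
      dx2 <- (cs - cx)^2
      sp2 <- outer(dy2, dx2, "+")
      inside <- sp2 <= S^2
      if (!any(inside)) next
      d2 <- sp2 + alpha * (img[ri, cj, drop = FALSE] - cg)^2
      d2[!inside] <- Inf
      win_best <- best[ri, cj, drop = FALSE]
      upd <- d2 < win_best
      if (any(upd)) {
        win_lab <- new_labels[ri, cj, drop = FALSE]
        win_best[upd] <- d2[upd]
        win_lab[upd] <- centers$label[ci]
        best[ri, cj] <- win_best
        new_labels[ri, cj] <- win_lab
      }
    }
    # keep the previous assignment when it is strictly better (or when a
    # pixel fell outside every window) -- guarantees monotone descent
    if (!anyNA(labels)) {
      prev_idx <- match(labels, centers$label)
      d_prev <- (px_x - centers$x[prev_idx])^2 + (px_y - centers$y[prev_idx])^2 +
        alpha * (img - centers$gs[prev_idx])^2
      keep <- d_prev < best
      new_labels[keep] <- labels[keep]
      best[keep] <- d_prev[keep]
    }
    if (anyNA(new_labels)) {
      miss <- which(is.na(new_labels))
      for (p in miss) {
        d2 <- (px_x[p] - centers$x)^2 + (px_y[p] - centers$y)^2 +
          alpha * (img[p] - centers$gs)^2
        j <- which.min(d2)
        new_labels[p] <- centers$label[j]
        best[p] <- d2[j]
      }
    }
    labels <- new_labels
    cost_trace <- c(cost_trace, sum(best))
    # center update: mean x, y, gs of the assigned pixels
    idx <- match(as.vector(labels), centers$label)
    sums <- rowsum(cbind(as.vector(px_x), as.vector(px_y), as.vector(img), 1),
                   group = idx)
    got <- as.integer(rownames(sums))
    new_centers <- centers
    nz <- sums[, 4] > 0
    new_centers$x[got[nz]] <- sums[nz, 1] / sums[nz, 4]
    new_centers$y[got[nz]] <- sums[nz, 2] / sums[nz, 4]
    new_centers$gs[got[nz]] <- sums[nz, 3] / sums[nz, 4]
    disp <- mean(sqrt((new_centers$x - centers$x)^2 + (new_centers$y - centers$y)^2))
    centers <- new_centers
    if (disp < cfg$conv_tol) { converged <- TRUE; break }
  }
  list(labels = labels, centers = centers, cost_trace = cost_trace,
       iterations = iters, converged = converged)
}

# Connected components of a label map under 4-connectivity.
# Returns an integer matrix of component ids (1-based).
.connected_components <- function(labels) {
  H <- nrow(labels); W <- ncol(labels); N <- H * W
  lv <- as.integer(labels)
  comp <- integer(N)
  next_id <- 0L
  row_of <- rep(seq_len(H), W)
  for (start in seq_len(N)) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    target <- lv[start]
    frontier <- start
    comp[start] <- next_id
    while (length(frontier) > 0L) {
      up <- frontier[row_of[frontier] > 1L] - 1L
      down <- frontier[row_of[frontier] < H] + 1L
      left <- frontier[frontier > H] - H
      right <- frontier[frontier <= N - H] + H
      nb <- c(up, down, left, right)
      nb <- nb[comp[nb] == 0L & lv[nb] == target]
      nb <- unique(nb)
      comp[nb] <- next_id
      frontier <- nb
    }
  }
  matrix(comp, H, W)
}

#' Merge undersized superpixels into their neighbors
#'
#' Connected components smaller than `min_size` pixels are absorbed into
#' the adjacent segment sharing the longest boundary (boundary length =
#' number of 4-adjacent pixel pairs; ties go to the smaller label). The
#' result is relabeled to consecutive 0-based labels in order of first
#' appearance (column-major scan).
#'
#' @param labels H x W integer label matrix.
#' @param min_size minimum segment size in pixels (>= 1).
#' @return list with `labels` (relabeled matrix) and `n_segments`.
#' @export
merge_small_superpixels <- function(labels, min_size = 1L) {
  if (min_size < 1L) stop("min_size must be >= 1")
  H <- nrow(labels); W <- ncol(labels); N <- H * W
  comp <- .connected_components(labels)
  cv <- as.integer(comp)
  lv <- as.integer(labels)
  repeat {
    sizes <- tabulate(cv)
    small <- which(sizes > 0L & sizes < min_size)
    if (length(small) == 0L || length(unique(cv)) == 1L) break
    # absorb the smallest offender first
    cid <- small[which.min(sizes[small])]
    members <- which(cv == cid)
    row_m <- ((members - 1L) %% H) + 1L
    nb <- c(members[row_m > 1L] - 1L, members[row_m < H] + 1L,
            members[members > H] - H, members[members <= N - H] + H)
    nb_comp <- cv[nb]
    nb_comp <- nb_comp[nb_comp != cid]
    if (length(nb_comp) == 0L) break
    counts <- table(nb_comp)
    top <- max(counts)
    cand <- as.integer(names(counts)[counts == top])
    # tie: prefer the neighbor with the smaller superpixel label
    cand_lab <- vapply(cand, function(cc) lv[match(cc, cv)], integer(1))
    tgt <- cand[which.min(cand_lab)]
    tgt_lab <- lv[match(tgt, cv)]
    cv[members] <- tgt
    lv[members] <- tgt_lab
  }
  first <- !duplicated(cv)
  relabel <- match(cv, cv[first])
  list(labels = matrix(relabel - 1L, H, W),
       n_segments = length(unique(relabel)))
}

#' Segment a grayscale image into superpixels
#'
#' Orchestrates the full modified-SLIC pipeline: histogram, maximum-entropy
#' thresholds, interval contrast enhancement, grid seeding, circular-window
#' clustering, and small-segment merging. Deterministic for a given image
#' and configuration.
#'
#' @param img grayscale matrix.
#' @param cfg a [slic_config()].
#' @return an object of class `slic_segmentation` with `labels`,
#'   `n_segments`, `centers`, `thresholds`, `enhanced` (the enhanced image),
#'   `boundary` (logical boundary matrix), `cost_trace`, `converged`.
#' @export
slic_segment <- function(img, cfg = slic_config()) {
  assert_gray_image(img)
  hist <- image_histogram(img)
  th <- tryCatch(max_entropy_thresholds(hist, cfg$k_thresholds),
                 error = function(e) integer(0))
  enhanced <- if (cfg$enhance) contrast_enhance(img, th, cfg$r_power) else img
  centers <- grid_init_centers(enhanced, cfg$M)
  fit <- slic_iterate(enhanced, centers, cfg)
  S <- sqrt(length(img) / cfg$M)
  min_size <- max(1L, floor(cfg$min_size_frac * S^2))
  merged <- merge_small_superpixels(fit$labels, min_size)
  structure(list(labels = merged$labels, n_segments = merged$n_segments,
                 centers = fit$centers, thresholds = th, enhanced = enhanced,
                 boundary = label_boundaries(merged$labels),
                 cost_trace = fit$cost_trace, converged = fit$converged),
            class = "slic_segmentation")
}

#' @export
print.slic_segmentation <- function(x, ...) {
  cat("SLIC segmentation:", nrow(x$labels), "x", ncol(x$labels), "image,",
      x$n_segments, "superpixels\n")
  cat("  thresholds:", if (length(x$thresholds)) paste(x$thresholds, collapse = ", ")
      else "(none)", "\n")
  cat("  iterations:", length(x$cost_trace),
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Boundary pixels of a label map
#'
#' A pixel is a boundary pixel when its label differs from its right or
#' lower 4-neighbor (either side of the edge is marked).
#'
#' @param labels H x W integer label matrix.
#' @return logical H x W matrix.
#' @export
label_boundaries <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  b <- matrix(FALSE, H, W)
  dh <- labels[-H, , drop = FALSE] != labels[-1, , drop = FALSE]
  dv <- labels[, -W, drop = FALSE] != labels[, -1, drop = FALSE]
  b[-H, ][dh] <- TRUE; b[-1, ][dh] <- TRUE
  b[, -W][dv] <- TRUE; b[, -1][dv] <- TRUE
  b
}

#' Boundary overlay image
#'
#' The (enhanced) image with superpixel boundaries painted white.
#'
#' @param seg a `slic_segmentation`.
#' @return grayscale matrix in \[0, 255\].
#' @export
boundary_overlay <- function(seg) {
  img <- seg$enhanced
  img[seg$boundary] <- 255
  img
}

# Otsu threshold from a 256-bin probability histogram: maximizes the
# between-class variance over all split points.
.otsu_threshold <- function(hist) {
  levels <- 0:255
  w <- cumsum(hist)
  mu <- cumsum(hist * levels)
  mu_t <- mu[256]
  sigma_b <- (mu_t * w - mu)^2 / (w * (1 - w))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  levels[which.max(sigma_b[1:255])]
}

#' Region-of-interest mask from a segmentation
#'
#' Keeps superpixels whose mean enhanced intensity falls below the global
#' Otsu threshold of the enhanced image — a stand-in rule selecting
#' nuclei-dense (dark) tissue regions.
#'
#' @param seg a `slic_segmentation`.
#' @return logical H x W matrix (TRUE = inside the ROI).
#' @export
roi_mask <- function(seg) {
  hist <- image_histogram(seg$enhanced)
  thr <- .otsu_threshold(hist)
  means <- tapply(as.vector(seg$enhanced), as.vector(seg$labels), mean)
  keep <- as.integer(names(means))[means < thr]
  matrix(as.vector(seg$labels) %in% keep, nrow(seg$labels), ncol(seg$labels))
}
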