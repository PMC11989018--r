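# Synthetic fixtures: histology-like two-class blob-texture images with
# pixel-level ground truth, class-structured backbone feature triplets
# with positive (ReLU-like) skew, and benchmark fitness functions for the
# optimizers. Every generator is deterministic under its seed.
#
# The image model emulates H&E-like tissue at a coarse level: a bright
# stained background whose mean brightness varies image to image (stain
# variability), faint mid-intensity stromal clutter blobs common to both
# classes, dark elliptical nuclei with sinusoidally perturbed boundaries,
# and additive Gaussian pixel noise. The abnormal (ACA) class has slightly
# more and substantially more irregular nuclei than the benign class, so
# the discriminative signal is mostly morphological (nuclear shape), not a
# gross intensity difference.

#' Synthetic image specification
#'
#' @param size image height/width in pixels (square).
#' @param n_nuclei number of nuclei to place (NULL = class default:
#'   8 benign, 10 ACA).
#' @param radius_range min/max nucleus semi-axis in pixels.
#' @param background_mean,nucleus_mean intensity means in \[0, 255\].
#' @param background_jitter_sd per-image SD of the background brightness
#'   (eosin stain variability).
#' @param nucleus_jitter_sd per-image SD of the nucleus intensity
#'   (hematoxylin stain variability); this is what defeats fixed-threshold
#'   global statistics and rewards adaptive, segmentation-based ones.
#' @param noise_sd pixel noise SD.
#' @param irregularity boundary perturbation amplitude in \[0, 1\]
#'   (NULL = class default: 0.12 benign, 0.55 ACA).
#' @param clutter_range min/max count of mid-intensity stromal blobs
#'   (class-independent texture confounding global statistics).
#' @param clutter_mean stromal blob intensity.
#' @param class `"benign"` or `"aca"`.
#' @param seed RNG seed.
#' @return a `synth_image_spec` list.
#' @export
synth_image_spec <- function(size = 64L, n_nuclei = NULL,
                             radius_range = c(4, 8), background_mean = 180,
                             nucleus_mean = 90, background_jitter_sd = 12,
                             nucleus_jitter_sd = 20, noise_sd = 18,
                             irregularity = NULL,
                             clutter_range = c(4L, 10L), clutter_mean = 150,
                             class = c("benign", "aca"), seed = 1L) {
  class <- match.arg(class)
  if (is.null(n_nuclei)) n_nuclei <- if (class == "benign") 8L else 10L
  if (is.null(irregularity)) irregularity <- if (class == "benign") 0.12 else 0.55
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (irregularity < 0 || irregularity > 1) stop("irregularity must lie in [0, 1]")
  if (max(radius_range) * 2 >= size) stop("nuclei do not fit within the image")
  structure(list(size = as.integer(size), n_nuclei = as.integer(n_nuclei),
                 radius_range = radius_range, background_mean = background_mean,
                 nucleus_mean = nucleus_mean,
                 background_jitter_sd = background_jitter_sd,
                 nucleus_jitter_sd = nucleus_jitter_sd,
                 noise_sd = noise_sd, irregularity = irregularity,
                 clutter_range = as.integer(clutter_range),
                 clutter_mean = clutter_mean,
                 class = class, seed = as.integer(seed)),
            class = "synth_image_spec")
}

#' Generate a synthetic histology-like image
#'
#' @param spec a [synth_image_spec()].
#' @return list with `image` (grayscale matrix in \[0, 255\]) and `mask`
#'   (logical ground-truth nucleus mask).
#' @export
make_image <- function(spec) {
  H <- spec$size; W <- spec$size
  with_seed(spec$seed, {
    bg <- spec$background_mean + stats::rnorm(1, 0, spec$background_jitter_sd)
    nuc <- spec$nucleus_mean + stats::rnorm(1, 0, spec$nucleus_jitter_sd)
    img <- matrix(bg, H, W)
    mask <- matrix(FALSE, H, W)
    yy <- matrix(rep(seq_len(H), W), H, W)
    xx <- matrix(rep(seq_len(W), each = H), H, W)
    # stromal clutter: hard-edged mid-intensity disks, identical
    # distribution in both classes; they contaminate global histogram and
    # gradient statistics without touching the ground-truth nucleus mask
    n_clutter <- sample(spec$clutter_range[1]:spec$clutter_range[2], 1L)
    for (i in seq_len(n_clutter)) {
      r <- stats::runif(1, 3, 10)
      cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
      d2 <- ((xx - cx)^2 + (yy - cy)^2) / r^2
      img[d2 <= 1] <- spec$clutter_mean + (bg - spec$background_mean) / 2
    }
    placed <- 0L; attempts <- 0L
    centers <- NULL
    while (placed < spec$n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > 200L * max(1L, spec$n_nuclei)) {
        stop("overcrowded spec: could not place ", spec$n_nuclei, " nuclei")
      }
      a <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      b <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      rmax <- max(a, b) * (1 + 0.35 * spec$irregularity)
      cx <- stats::runif(1, rmax + 1, W - rmax)
      cy <- stats::runif(1, rmax + 1, H - rmax)
      if (!is.null(centers) &&
          any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 < (0.8 * (a + b))^2)) {
        next
      }
      theta <- stats::runif(1, 0, pi)
      lobes <- sample(3:6, 1)
      phase <- stats::runif(1, 0, 2 * pi)
      u <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
      v <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
      rho <- sqrt((u / a)^2 + (v / b)^2)
      ang <- atan2(v, u)
      inside <- rho <= 1 + 0.35 * spec$irregularity * sin(lobes * ang + phase)
      img[inside] <- nuc
      mask <- mask | inside
      centers <- rbind(centers, c(cx, cy))
      placed <- placed + 1L
    }
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    list(image = clip(img, 0, 255), mask = mask)
  })
}

# Map a target moment skewness to the sdlog of a lognormal (monotone).
.lognormal_sdlog <- function(skew) {
  if (skew <= 0) stop("target skewness must be positive")
  g <- function(s) {
    w <- exp(s^2)
    (w + 2) * sqrt(w - 1) - skew
  }
  stats::uniroot(g, c(1e-4, 3))$root
}

#' Synthetic feature-triplet specification
#'
#' @param n_per_class images per class.
#' @param dim feature dimension (default 2048).
#' @param n_informative number of class-informative features (`<= dim`).
#' @param class_shift additive shift of informative features in the
#'   abnormal class (per-feature effect size; default 1).
#' @param backbone_cor cross-backbone correlation of the shared noise in
#'   \[0, 1\].
#' @param skew target positive skewness of the (lognormal) feature noise,
#'   mimicking ReLU-activation distributions.
#' @param seed RNG seed.
#' @return a `synth_feature_spec` list.
#' @export
synth_feature_spec <- function(n_per_class = 30L, dim = 2048L,
                               n_informative = 10L, class_shift = 1,
                               backbone_cor = 0.8, skew = 4, seed = 1L) {
  if (n_informative > dim) stop("n_informative must not exceed dim")
  if (backbone_cor < 0 || backbone_cor > 1) stop("backbone_cor must lie in [0, 1]")
  structure(list(n_per_class = as.integer(n_per_class), dim = as.integer(dim),
                 n_informative = as.integer(n_informative),
                 class_shift = class_shift, backbone_cor = backbone_cor,
                 skew = skew, seed = as.integer(seed)),
            class = "synth_feature_spec")
}

#' Generate a correlated backbone feature triplet
#'
#' Three matrices standing in for the deep-feature outputs of three
#' backbones of increasing depth. Noise is lognormal (positively skewed,
#' like ReLU activations) and correlated across backbones on the log scale
#' with correlation `backbone_cor`; the first `n_informative` columns gain
#' an additive `class_shift` in the abnormal class, identically in all
#' three backbones. Values are clipped at 0.
#'
#' @param spec a [synth_feature_spec()].
#' @return list with `f50`, `f101`, `f152` (feature matrices), `labels`
#'   (0/1, balanced), `informative` (column indices carrying the signal).
#' @export
make_feature_triplet <- function(spec) {
  n <- 2L * spec$n_per_class
  d <- spec$dim
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  sdlog <- .lognormal_sdlog(spec$skew)
  with_seed(spec$seed, {
    shared <- matrix(stats::rnorm(n * d), n, d)
    rho <- spec$backbone_cor
    backbone <- function() {
      own <- matrix(stats::rnorm(n * d), n, d)
      z <- sqrt(rho) * shared + sqrt(1 - rho) * own
      m <- exp(sdlog * z - sdlog^2 / 2)          # lognormal, mean 1
      m[, seq_len(spec$n_informative)] <-
        m[, seq_len(spec$n_informative), drop = FALSE] +
        spec$class_shift * (labels == 1L)
      pmax(m, 0)
    }
    list(f50 = backbone(), f101 = backbone(), f152 = backbone(),
         labels = labels, informative = seq_len(spec$n_informative))
  })
}

#' Benchmark fitness functions with known optima
#'
#' `sphere`: `f(x) = -sum(x^2)` on the unit box, maximum 0 at the origin.
#' `rastrigin`: `f(x) = -(10 d + sum(x^2 - 10 cos(2 pi x)))` on
#' \[-5.12, 5.12\]^d, maximum 0 at the origin.
#' `planted_subset`: positions decode to masks via [position_to_mask()];
#' the fitness is the fraction of planted feature indices selected, so the
#' exact planted mask attains the optimum 1.
#'
#' @param name benchmark name.
#' @param dim dimension.
#' @param planted for `planted_subset`: indices of the planted features.
#' @return list with `f`, `lower`, `upper`, `optimum` (the maximal value),
#'   and `argmax` (an optimizing position, where meaningful).
#' @export
benchmark_fitness <- function(name = c("sphere", "rastrigin", "planted_subset"),
                              dim = 5L, planted = NULL) {
  name <- match.arg(name)
  switch(name,
    sphere = list(
      f = function(x) -sum(x^2),
      lower = -1, upper = 1, optimum = 0, argmax = rep(0, dim)
    ),
    rastrigin = list(
      f = function(x) -(10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))),
      lower = -5.12, upper = 5.12, optimum = 0, argmax = rep(0, dim)
    ),
    planted_subset = {
      if (is.null(planted)) stop("planted indices required")
      list(
        f = function(x) {
          mask <- position_to_mask(x)
          mean(mask[planted])
        },
        lower = -4, upper = 4, optimum = 1,
        argmax = ifelse(seq_len(dim) %in% planted, 4, -4)
      )
    }
  )
}

#' Boundary recall of a segmentation against a ground-truth mask
#'
#' The fraction of ground-truth boundary pixels lying within `tol` pixels
#' (Chebyshev distance) of a predicted segment boundary — the standard
#' superpixel boundary-adherence score.
#'
#' @param labels predicted label matrix.
#' @param truth_mask logical ground-truth mask.
#' @param tol distance tolerance in pixels (default 2).
#' @return boundary recall in \[0, 1\] (1 when the truth has no boundary).
#' @export
boundary_recall <- function(labels, truth_mask, tol = 2L) {
  gt <- label_boundaries(truth_mask * 1L)
  if (!any(gt)) return(1)
  pred <- label_boundaries(labels)
  # dilate the predicted boundary by tol (Chebyshev)
  H <- nrow(pred); W <- ncol(pred)
  dil <- matrix(FALSE, H, W)
  for (dy in -tol:tol) {
    rs <- clip(seq_len(H) + dy, 1L, H)
    for (dx in -tol:tol) {
      cs <- clip(seq_len(W) + dx, 1L, W)
      dil <- dil | pred[rs, cs, drop = FALSE]
    }
  }
  mean(dil[gt])
}
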