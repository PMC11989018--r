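# Shared fixtures and independent oracle helpers built in code.

# A 256-bin histogram with mass on the given intensities.
hist_at <- function(values, probs) {
  h <- rep(0, 256)
  h[values + 1L] <- probs
  h
}

# Random histogram occupying `bins` distinct intensity levels.
random_sparse_hist <- function(bins = 16L) {
  levels <- sort(sample(0:255, bins))
  mass <- stats::runif(bins) + 0.05
  hist_at(levels, mass / sum(mass))
}

# Independent Kapur criterion: sum over segments of the Shannon entropy of
# the conditional within-segment distribution (computed from first
# principles, not via segmented_entropy()).
kapur_oracle <- function(hist, th) {
  bounds <- c(0L, th + 1L, 256L)
  total <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    seg <- hist[(bounds[i] + 1L):bounds[i + 1L]]
    P <- sum(seg)
    if (P <= 0) return(-Inf)
    cond <- seg[seg > 0] / P
    total <- total - sum(cond * log(cond))
  }
  total
}

# Exhaustive maximum-entropy threshold search (k = 1 or 2), smallest
# lexicographic tie-break.
exhaustive_thresholds <- function(hist, k) {
  best_phi <- -Inf; best <- NULL
  if (k == 1L) {
    for (t in 0:254) {
      phi <- kapur_oracle(hist, t)
      if (is.finite(phi) && phi > best_phi + 1e-12) { best_phi <- phi; best <- t }
    }
  } else {
    for (t1 in 0:253) for (t2 in (t1 + 1L):254L) {
      phi <- kapur_oracle(hist, c(t1, t2))
      if (is.finite(phi) && phi > best_phi + 1e-12) { best_phi <- phi; best <- c(t1, t2) }
    }
  }
  best
}

# Small deterministic grayscale test image with smooth structure.
ramp_image <- function(h = 20L, w = 20L, lo = 60, hi = 120) {
  outer(seq(lo, hi, length.out = h), seq(0, 1, length.out = w),
        function(a, b) a + 10 * b)
}

# Tiny labeled feature set: two Gaussian blobs.
blob_data <- function(n_per_class = 20L, d = 2L, shift = 3, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * d), n_per_class, d),
             matrix(stats::rnorm(n_per_class * d, mean = shift), n_per_class, d))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}
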