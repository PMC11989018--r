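# Kapur maximum-entropy multilevel thresholding and piecewise power-law
# contrast enhancement — the preprocessing stages of the modified SLIC
# segmenter.

#' Grayscale probability histogram
#'
#' @param img grayscale matrix; intensities are rounded to the 0..255 bins.
#' @return numeric vector of 256 probabilities summing to 1.
#' @export
image_histogram <- function(img) {
  assert_gray_image(img)
  counts <- tabulate(as.integer(round(img)) + 1L, nbins = 256L)
  counts / length(img)
}

# Segment boundaries for thresholds t (values in 0..254): bins [0..t1],
# [t1+1..t2], ..., [tk+1..255]. Returns a list of index ranges (1-based bins).
.threshold_segments <- function(th) {
  lo <- c(0L, th + 1L)
  hi <- c(th, 255L)
  Map(function(a, b) seq.int(a + 1L, b + 1L), lo, hi)
}

#' Kapur segmented entropy of a histogram under a threshold set
#'
#' For thresholds t1 < ... < tk the histogram is cut into k + 1 segments
#' and the criterion is the sum over segments of
#' `log(P) - sum(p * log(p)) / P`, where `P` is the segment's total mass —
#' i.e. the sum of the Shannon entropies of the within-segment conditional
#' distributions. `0 * log(0)` is taken as 0. Natural logarithms.
#'
#' @param hist 256-bin probability vector.
#' @param th strictly increasing integer thresholds in 0..254.
#' @return the entropy criterion (a real number).
#' @export
segmented_entropy <- function(hist, th) {
  .assert_histogram(hist)
  .assert_thresholds(th)
  plogp <- ifelse(hist > 0, hist * log(hist), 0)
  segs <- .threshold_segments(th)
  phi <- 0
  for (s in segs) {
    P <- sum(hist[s])
    if (P <= 0) stop("infeasible thresholds: a segment has zero mass")
    phi <- phi + log(P) - sum(plogp[s]) / P
  }
  phi
}

.assert_histogram <- function(hist) {
  if (length(hist) != 256L) stop("histogram must have 256 bins")
  if (any(hist < 0)) stop("histogram probabilities must be non-negative")
  if (abs(sum(hist) - 1) > 1e-9) stop("histogram must sum to 1")
  invisible(hist)
}

.assert_thresholds <- function(th) {
  if (length(th) < 1L) stop("at least one threshold required")
  if (any(th != round(th)) || any(th < 0L) || any(th > 254L)) {
    stop("thresholds must be integers in 0..254")
  }
  if (length(th) > 1L && any(diff(th) <= 0)) stop("thresholds must be strictly increasing")
  invisible(th)
}

#' Maximum-entropy multilevel thresholds
#'
#' Maximizes [segmented_entropy()] over threshold tuples. For k <= 2 the
#' search is exhaustive (exact); for k >= 3 coordinate ascent from a
#' quantile initialization sweeps one threshold at a time, which never
#' decreases the criterion, until a full sweep makes no change. Ties are
#' broken toward the lexicographically smallest tuple.
#'
#' @param hist 256-bin probability vector.
#' @param k number of thresholds (1..4).
#' @return sorted integer vector of k thresholds.
#' @export
max_entropy_thresholds <- function(hist, k) {
  .assert_histogram(hist)
  if (k < 1L || k > 4L) stop("k must be between 1 and 4")
  occupied <- which(hist > 0) - 1L          # intensity values with mass
  if (length(occupied) < k + 1L) {
    stop("histogram has fewer non-empty bins (", length(occupied),
         ") than segments (", k + 1L, ")")
  }
  plogp <- ifelse(hist > 0, hist * log(hist), 0)
  cp <- c(0, cumsum(hist))                  # cp[i+1] = sum of bins 0..i-1
  cq <- c(0, cumsum(plogp))
  # Segment term for bins a..b (intensities, inclusive); -Inf when empty.
  seg_term <- function(a, b) {
    P <- cp[b + 2L] - cp[a + 1L]
    ifelse(P > 0, log(P) - (cq[b + 2L] - cq[a + 1L]) / P, -Inf)
  }
  if (k == 1L) {
    t_cand <- 0:254
    phi <- seg_term(0L, t_cand) + seg_term(t_cand + 1L, 255L)
    best <- which.max(phi)                  # which.max returns the first max
    return(t_cand[best])
  }
  if (k == 2L) {
    best_phi <- -Inf; best_t <- NULL
    lower <- seg_term(0L, 0:253)
    for (t1 in 0:253) {
      if (!is.finite(lower[t1 + 1L])) next
      t2 <- (t1 + 1L):254L
      phi <- lower[t1 + 1L] + seg_term(t1 + 1L, t2) + seg_term(t2 + 1L, 255L)
      i <- which.max(phi)
      if (is.finite(phi[i]) && phi[i] > best_phi + 1e-12) {
        best_phi <- phi[i]; best_t <- c(t1, t2[i])
      }
    }
    if (is.null(best_t)) stop("no feasible threshold pair")
    return(best_t)
  }
  # k >= 3: quantile initialization + coordinate ascent
  cum <- cumsum(hist)
  th <- vapply(seq_len(k) / (k + 1), function(q) {
    min(which(cum >= q)) - 1L
  }, integer(1))
  th <- pmin(pmax(th, 0L), 254L)
  # force strict increase
  for (i in seq_len(k)) if (i > 1L && th[i] <= th[i - 1L]) th[i] <- th[i - 1L] + 1L
  th <- pmin(th, 254L - (k - seq_len(k)))
  phi_of <- function(th) {
    lo <- c(0L, th + 1L); hi <- c(th, 255L)
    sum(vapply(seq_along(lo), function(i) seg_term(lo[i], hi[i]), numeric(1)))
  }
  best_phi <- phi_of(th)
  if (!is.finite(best_phi)) {
    # nudge to a feasible start: spread across occupied bins
    th <- occupied[round(seq_len(k) * (length(occupied) - 1) / (k + 1)) + 1L]
    th <- sort(unique(pmin(th, 254L)))
    while (length(th) < k) th <- sort(unique(c(th, max(th) + 1L)))
    best_phi <- phi_of(th)
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) {
      lo <- if (i == 1L) 0L else th[i - 1L] + 1L
      hi <- if (i == k) 254L else th[i + 1L] - 1L
      cand <- lo:hi
      phis <- vapply(cand, function(t) {
        tt <- th; tt[i] <- t; phi_of(tt)
      }, numeric(1))
      j <- which.max(phis)
      if (is.finite(phis[j]) && (phis[j] > best_phi + 1e-12 ||
          (phis[j] >= best_phi - 1e-12 && cand[j] < th[i]))) {
        if (phis[j] > best_phi + 1e-12 || cand[j] < th[i]) {
          changed <- changed || (cand[j] != th[i])
          th[i] <- cand[j]
          best_phi <- phis[j]
        }
      }
    }
    if (!changed) break
  }
  th
}

#' Probability-weighted turning point of an intensity interval
#'
#' The centroid `sum(x * p(x)) / sum(p(x))` of the histogram mass inside
#' `[x_lo, x_hi]` (intensities, inclusive).
#'
#' @param hist 256-bin probability vector.
#' @param x_lo,x_hi interval bounds in 0..255.
#' @return the turning point (a real number in `[x_lo, x_hi]`).
#' @export
interval_turning_point <- function(hist, x_lo, x_hi) {
  .assert_histogram(hist)
  idx <- seq.int(x_lo, x_hi) + 1L
  mass <- sum(hist[idx])
  if (mass <= 0) stop("interval [", x_lo, ", ", x_hi, "] contains no mass")
  sum((idx - 1L) * hist[idx]) / mass
}

#' Power-law enhancement curve coefficients
#'
#' Fits `f(x) = a * x^r + b` through the endpoints
#' `(x_lo, y_lo)` and `(x_hi, y_hi)`.
#'
#' @param x_lo,x_hi source interval bounds (`x_hi > x_lo >= 1`).
#' @param y_lo,y_hi target interval bounds (`y_hi > y_lo`).
#' @param r power exponent (>= 1).
#' @return list with elements `a` and `b`.
#' @export
enhancement_curve <- function(x_lo, x_hi, y_lo, y_hi, r) {
  if (x_hi <= x_lo || x_lo < 1) stop("require x_hi > x_lo >= 1")
  if (y_hi <= y_lo) stop("require y_hi > y_lo")
  if (r < 1) stop("require r >= 1")
  den <- x_hi^r - x_lo^r
  if (abs(den) < 1e-12) stop("degenerate interval: x_hi^r equals x_lo^r")
  a <- (y_hi - y_lo) / den
  b <- y_lo - a * x_lo^r
  list(a = a, b = b)
}

# Monotone map of the interval [x_lo, x_hi] -> [y_lo, y_hi], convex (power
# curve) below the turning point x_m and concave (reflected power curve)
# above it, with f(x_m) = (y_lo + y_hi) / 2. Falls back to a single curve
# when the turning point hugs an endpoint. Returns f evaluated at `x`.
.interval_map <- function(x, x_lo, x_hi, y_lo, y_hi, x_m, r) {
  if (x_hi - x_lo < 1) return(rep((y_lo + y_hi) / 2, length(x)))
  y_m <- (y_lo + y_hi) / 2
  # r = 1 is a plain linear stretch; the turning-point split is vacuous there
  if (r == 1 || x_m - x_lo < 0.5 || x_hi - x_m < 0.5) {
    cf <- enhancement_curve(x_lo, x_hi, y_lo, y_hi, r)
    return(cf$a * x^r + cf$b)
  }
  lo_cf <- enhancement_curve(x_lo, x_m, y_lo, y_m, r)
  up_cf <- enhancement_curve(x_m, x_hi, y_m, y_hi, r)
  out <- numeric(length(x))
  low <- x <= x_m
  out[low] <- lo_cf$a * x[low]^r + lo_cf$b
  # reflect the convex upper curve about the interval midpoint -> concave
  xr <- x_m + x_hi - x[!low]
  out[!low] <- (y_m + y_hi) - (up_cf$a * xr^r + up_cf$b)
  out
}

#' Entropy-guided interval contrast enhancement
#'
#' Intensities are clamped to >= 1 (the power-curve domain), the range
#' `[1, 255]` is cut at the supplied thresholds, and each source interval is
#' mapped onto equal-width target intervals partitioning `[1, 255]` by a
#' two-piece power curve: convex up to the interval's probability-weighted
#' turning point, concave beyond it, with the turning point sent to the
#' target interval's midpoint. The overall transform is monotone
#' non-decreasing and output is clipped to `[0, 255]`.
#'
#' @param img grayscale matrix.
#' @param th thresholds from [max_entropy_thresholds()] (may be empty, in
#'   which case a single interval spans the whole range).
#' @param r power exponent (>= 1, default 2).
#' @return enhanced grayscale matrix (integer-valued).
#' @export
contrast_enhance <- function(img, th, r = 2) {
  assert_gray_image(img)
  if (r < 1) stop("require r >= 1")
  clamped <- pmax(round(img), 1)
  hist <- image_histogram(clamped)
  th <- as.integer(th[th >= 1 & th <= 254])
  bx <- unique(c(1, sort(th), 255))
  n_int <- length(bx) - 1L
  by <- seq(1, 255, length.out = n_int + 1L)
  lut <- numeric(256)          # value v maps to lut[v + 1]
  for (i in seq_len(n_int)) {
    x_lo <- bx[i]; x_hi <- bx[i + 1L]
    mass <- sum(hist[(x_lo:x_hi) + 1L])
    x_m <- if (mass > 0) interval_turning_point(hist, x_lo, x_hi) else (x_lo + x_hi) / 2
    vals <- x_lo:x_hi
    lut[vals + 1L] <- .interval_map(vals, x_lo, x_hi, by[i], by[i + 1L], x_m, r)
  }
  lut[1L] <- lut[2L]           # intensity 0 is clamped to 1
  out <- matrix(lut[clamped + 1L], nrow(img), ncol(img))
  round(pmin(pmax(out, 0), 255))
}
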