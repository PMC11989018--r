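# Entropy diagnostics for selected feature sets: approximate entropy,
# Shannon entropy, and fuzzy entropy. Natural logarithms throughout.

# Embed a series into templates of length n: (M - n + 1) x n matrix.
.templates <- function(x, n) {
  M <- length(x)
  idx <- outer(seq_len(M - n + 1L) - 1L, seq_len(n), "+")
  matrix(x[idx], M - n + 1L, n)
}

# Chebyshev distance matrix between template rows.
.cheb_dist <- function(tm) {
  m <- nrow(tm)
  d <- matrix(0, m, m)
  for (j in seq_len(ncol(tm))) {
    d <- pmax(d, abs(outer(tm[, j], tm[, j], "-")))
  }
  d
}

#' Approximate entropy of a series
#'
#' `AE = ln(B^n(r) / B^{n+1}(r))`, where `B^n(r)` is the mean over
#' templates of length n of the fraction of templates within Chebyshev
#' distance `r_tol` (self-matches included, so `B` is always positive and
#' constant series give exactly 0).
#'
#' @param x numeric series of length > n + 1.
#' @param n template length (default 2).
#' @param r_tol match tolerance; default 0.2 times the series SD (0.2 when
#'   the series is constant).
#' @return the approximate entropy (>= 0 up to floating error); `Inf` with
#'   a warning if a match count vanishes (cannot happen with self-matches).
#' @export
approximate_entropy <- function(x, n = 2L, r_tol = NULL) {
  M <- length(x)
  if (M <= n + 1L) stop("series too short for template length ", n)
  if (is.null(r_tol)) {
    s <- stats::sd(x)
    r_tol <- if (is.finite(s) && s > 0) 0.2 * s else 0.2
  }
  if (r_tol <= 0) stop("r_tol must be positive")
  frac <- function(len) {
    tm <- .templates(x, len)
    d <- .cheb_dist(tm)
    mean(rowMeans(d <= r_tol))
  }
  b_n <- frac(n)
  b_n1 <- frac(n + 1L)
  if (b_n1 == 0) { warning("zero match count at length n + 1"); return(Inf) }
  log(b_n / b_n1)
}

#' Shannon entropy
#'
#' `-sum(p * log(p))` with `0 * log(0) = 0`. Raw value vectors are first
#' histogrammed over `bins` equal-width bins spanning their range.
#'
#' @param x probability vector (`input = "prob"`, must sum to 1) or raw
#'   values (`input = "values"`).
#' @param input interpretation of `x`.
#' @param bins number of histogram bins for raw values.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(x, input = c("prob", "values"), bins = 32L) {
  input <- match.arg(input)
  if (input == "values") {
    rng <- range(x)
    if (diff(rng) == 0) return(0)
    counts <- tabulate(pmin(bins, 1L + floor((x - rng[1]) / diff(rng) * bins)),
                       nbins = bins)
    x <- counts / sum(counts)
  } else {
    if (any(x < 0)) stop("probabilities must be non-negative")
    if (abs(sum(x) - 1) > 1e-9) stop("probabilities must sum to 1")
  }
  -sum(ifelse(x > 0, x * log(x), 0))
}

#' Fuzzy entropy of a series
#'
#' `FE = ln(phi^n / phi^{n+1})`, where `phi^n` averages the pairwise fuzzy
#' memberships `exp(-d^2 / width)` over all ordered template pairs
#' `p != q`; templates are mean-subtracted and compared by Chebyshev
#' distance. Constant series give exactly 0.
#'
#' @param x numeric series of length > n + 1.
#' @param n template length (default 2).
#' @param width membership width (default 0.25).
#' @return the fuzzy entropy.
#' @export
fuzzy_entropy <- function(x, n = 2L, width = 0.25) {
  M <- length(x)
  if (M <= n + 1L) stop("series too short for template length ", n)
  if (width <= 0) stop("width must be positive")
  phi <- function(len) {
    tm <- .templates(x, len)
    tm <- tm[-nrow(tm), , drop = FALSE]   # M - n templates, as defined
    tm <- tm - rowMeans(tm)
    d <- .cheb_dist(tm)
    memb <- exp(-d^2 / width)
    m <- nrow(tm)
    if (m < 2L) stop("series too short for template length ", len)
    (sum(memb) - m) / (m * (m - 1L))   # exclude self-pairs (membership 1)
  }
  log(phi(n) / phi(n + 1L))
}
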