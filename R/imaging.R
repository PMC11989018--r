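# Image containers and preprocessing.
#
# A grayscale image is a plain numeric H x W matrix with intensities in
# [0, 255]; a color image is an H x W x 3 array on the same scale. Row index
# is y (top to bottom), column index is x, both 0-based in all coordinate
# interfaces.

#' Validate a color image
#'
#' @param img an H x W x 3 numeric array with channel values in \[0, 255\].
#' @return `img`, invisibly, after validation.
#' @export
assert_color_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("color image must be an H x W x 3 array (got ",
         paste(dim(img), collapse = "x"), ")")
  }
  if (dim(img)[1] < 8L || dim(img)[2] < 8L) {
    stop("image dimensions must be at least 8 x 8")
  }
  if (anyNA(img) || any(!is.finite(img))) stop("image contains non-finite values")
  if (min(img) < 0 || max(img) > 255) stop("channel values must lie in [0, 255]")
  invisible(img)
}

#' Validate a grayscale image
#'
#' @param img an H x W numeric matrix with values in \[0, 255\].
#' @return `img`, invisibly, after validation.
#' @export
assert_gray_image <- function(img) {
  if (!is.matrix(img)) stop("grayscale image must be a matrix")
  if (anyNA(img) || any(!is.finite(img))) stop("image contains non-finite values")
  if (min(img) < 0 || max(img) > 255) stop("intensities must lie in [0, 255]")
  invisible(img)
}

#' Convert a color image to grayscale
#'
#' Weighted luma conversion with BT.601 coefficients
#' (0.299 R + 0.587 G + 0.114 B), rounded to integer intensities.
#'
#' @param img an H x W x 3 array in \[0, 255\].
#' @return an H x W grayscale matrix in \[0, 255\].
#' @export
to_grayscale <- function(img) {
  assert_color_image(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  round(pmin(pmax(g, 0), 255))
}

# Reflect (mirror) index vector for positions 1..n extended by pad on each side.
reflect_index <- function(n, pad) {
  idx <- seq.int(1 - pad, n + pad)
  # reflect without repeating the edge sample: 0 -> 2, -1 -> 3, n+1 -> n-1 ...
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  pmin(pmax(idx, 1L), n)
}

#' Resize an image with bilinear interpolation
#'
#' Pixel-center alignment: output pixel (r, c) samples the source at
#' ((r + 0.5) * H/h - 0.5, (c + 0.5) * W/w - 0.5) in 0-based coordinates,
#' clamped to the source grid. An identity resize reproduces the input
#' exactly, and constant images stay constant.
#'
#' @param img grayscale matrix or H x W x 3 color array.
#' @param h,w target dimensions (both >= 8 for full images; >= 1 accepted for
#'   internal use on patches).
#' @return the resized image of the same kind as the input.
#' @export
resize_image <- function(img, h, w) {
  if (h < 1 || w < 1) stop("target dimensions must be positive")
  if (is.matrix(img)) return(.resize_plane(img, h, w))
  if (is.array(img) && length(dim(img)) == 3L) {
    out <- array(0, dim = c(h, w, dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- .resize_plane(img[, , ch], h, w)
    return(out)
  }
  stop("img must be a matrix or a 3-d array")
}

.resize_plane <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  sy <- (seq_len(h) - 0.5) * H / h - 0.5   # 0-based source rows
  sx <- (seq_len(w) - 0.5) * W / w - 0.5
  sy <- pmin(pmax(sy, 0), H - 1)
  sx <- pmin(pmax(sx, 0), W - 1)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  fy <- sy - y0; fx <- sx - x0
  a <- m[cbind(rep(y0 + 1, times = w), rep(x0 + 1, each = h))]
  b <- m[cbind(rep(y0 + 1, times = w), rep(x1 + 1, each = h))]
  c_ <- m[cbind(rep(y1 + 1, times = w), rep(x0 + 1, each = h))]
  d <- m[cbind(rep(y1 + 1, times = w), rep(x1 + 1, each = h))]
  wy <- rep(fy, times = w); wx <- rep(fx, each = h)
  v <- a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
    c_ * wy * (1 - wx) + d * wy * wx
  matrix(v, nrow = h, ncol = w)
}

#' Adaptive fuzzy denoising filter
#'
#' Each output pixel is the fuzzy-membership-weighted mean of its window:
#' the weight of a neighbor with intensity I_n relative to the window center
#' I_c is the Gaussian membership exp(-(I_n - I_c)^2 / (2 sigma^2)). Pixels
#' similar to the center dominate, so edges are preserved while noise within
#' homogeneous regions is averaged out. Borders use reflect padding.
#'
#' @param img grayscale matrix.
#' @param window odd window side length (>= 3).
#' @param sigma membership bandwidth in intensity units (> 0).
#' @return filtered grayscale matrix; its range is contained in the input range.
#' @export
adaptive_fuzzy_filter <- function(img, window = 3L, sigma = 30) {
  assert_gray_image(img)
  if (window < 3L || window %% 2L == 0L) stop("window must be an odd integer >= 3")
  if (sigma <= 0) stop("sigma must be positive")
  H <- nrow(img); W <- ncol(img)
  pad <- (window - 1L) %/% 2L
  ri <- reflect_index(H, pad)
  ci <- reflect_index(W, pad)
  padded <- img[ri, ci, drop = FALSE]
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  for (dy in 0:(window - 1L)) {
    for (dx in 0:(window - 1L)) {
      nb <- padded[dy + seq_len(H), dx + seq_len(W), drop = FALSE]
      wgt <- exp(-(nb - img)^2 / (2 * sigma^2))
      num <- num + wgt * nb
      den <- den + wgt
    }
  }
  num / den
}
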