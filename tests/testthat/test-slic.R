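# Grid seeding, the combined distance, the clustering loop, small-segment
# merging, and the end-to-end segmenter.

test_that("grid seeding places sqrt(N/M)-spaced centers and respects gradients", {
  const <- matrix(100, 100, 100)
  ctr <- grid_init_centers(const, 25)
  expect_equal(nrow(ctr), 25)                          # exact 5 x 5 grid
  expect_length(unique(ctr$x), 5)
  expect_true(all(diff(sort(unique(ctr$x))) == 20))    # spacing sqrt(N/M) = 20
  expect_true(all(diff(sort(unique(ctr$y))) == 20))

  # constant image: all gradients zero, ties keep the grid position
  ctr2 <- grid_init_centers(const, 16)
  expect_true(all(diff(sort(unique(ctr2$x))) == 25))

  # centers that start on an intensity edge relocate to a position whose
  # gradient is no larger than the grid position's (exhaustive 3x3 move)
  img <- matrix(0, 20, 20)
  img[, 11:20] <- 60
  grid_pos <- grid_init_centers(matrix(50, 20, 20), 16)  # ties: pure grid
  ctr3 <- grid_init_centers(img, 16)
  g <- slicfuse:::.gradient_magnitude(img)
  for (i in seq_len(nrow(ctr3))) {
    expect_lte(g[ctr3$y[i] + 1, ctr3$x[i] + 1],
               g[grid_pos$y[i] + 1, grid_pos$x[i] + 1] + 1e-12)
    expect_lte(max(abs(c(ctr3$y[i] - grid_pos$y[i], ctr3$x[i] - grid_pos$x[i]))), 1)
  }
  expect_error(grid_init_centers(matrix(0, 8, 8), 32), "M too large")
})

test_that("pixel distance composes spatial and grayscale terms", {
  c0 <- list(x = 0, y = 0, gs = 10)
  expect_equal(pixel_distance(c0, 0, 0, 10, 1), 0)
  expect_equal(pixel_distance(c0, 3, 4, 10, 0.7), 5)        # pure spatial 3-4-5
  expect_equal(pixel_distance(c0, 3, 4, 15, 1), sqrt(50))   # sqrt(25 + 25)
  expect_error(pixel_distance(c0, 1, 1, 5, 0), "alpha")
})

test_that("clustering on a constant image converges to a Voronoi partition", {
  const <- matrix(100, 40, 40)
  cfg <- slic_config(M = 16, enhance = FALSE)
  ctr <- grid_init_centers(const, 16)
  fit <- slic_iterate(const, ctr, cfg)
  expect_true(fit$converged)
  expect_equal(length(unique(as.vector(fit$labels))), 16)
  # labels equal nearest-seed assignment (spatial Voronoi; ties -> lower label)
  for (p in sample(1600, 50)) {
    y <- (p - 1) %% 40; x <- (p - 1) %/% 40
    d2 <- (ctr$x - x)^2 + (ctr$y - y)^2
    expect_equal(fit$labels[y + 1, x + 1], ctr$label[which.min(d2)])
  }
})

test_that("a strong intensity edge decides the boundary when alpha is large", {
  img <- matrix(0, 20, 20); img[, 13:20] <- 200
  cfg <- slic_config(M = 4, enhance = FALSE, alpha = 100)
  ctr <- data.frame(x = c(5, 15), y = c(10, 10), gs = c(0, 200), label = 0:1)
  fit <- slic_iterate(img, ctr, cfg)
  expect_true(all(fit$labels[, 1:12] == 0))
  expect_true(all(fit$labels[, 13:20] == 1))
})

test_that("the clustering loop matches a naive all-candidates oracle", {
  set.seed(3)
  img <- ramp_image(20, 20)
  M <- 4L
  cfg <- slic_config(M = M, compactness = 20, max_iter = 3, conv_tol = 0,
                     enhance = FALSE)
  ctr <- grid_init_centers(img, M)
  fit <- slic_iterate(img, ctr, cfg)

  # independent naive reimplementation: per pixel, loop over all centers
  # within the circular window (plus the pixel's current center), pick the
  # d'^2 argmin with lower-label ties; then means; repeat
  S <- sqrt(400 / M); alpha <- (S / 20)^2
  cc <- ctr; lab <- matrix(NA_integer_, 20, 20)
  for (it in 1:3) {
    newlab <- matrix(NA_integer_, 20, 20)
    for (y in 0:19) for (x in 0:19) {
      best <- Inf; bl <- NA_integer_
      for (ci in seq_len(nrow(cc))) {
        ds2 <- (cc$x[ci] - x)^2 + (cc$y[ci] - y)^2
        in_window <- ds2 <= S^2
        is_prev <- !is.na(lab[y + 1, x + 1]) && cc$label[ci] == lab[y + 1, x + 1]
        if (!in_window && !is_prev) next
        d2 <- ds2 + alpha * (cc$gs[ci] - img[y + 1, x + 1])^2
        if (d2 < best) { best <- d2; bl <- cc$label[ci] }
      }
      if (is.na(bl)) {             # uncovered: nearest by d'
        d2all <- (cc$x - x)^2 + (cc$y - y)^2 + alpha * (cc$gs - img[y + 1, x + 1])^2
        bl <- cc$label[which.min(d2all)]
      }
      newlab[y + 1, x + 1] <- bl
    }
    lab <- newlab
    for (ci in seq_len(nrow(cc))) {
      sel <- lab == cc$label[ci]
      if (any(sel)) {
        ys <- row(lab)[sel] - 1; xs <- col(lab)[sel] - 1
        cc$x[ci] <- mean(xs); cc$y[ci] <- mean(ys); cc$gs[ci] <- mean(img[sel])
      }
    }
  }
  expect_identical(fit$labels, lab)
})

test_that("assignment-phase cost is non-increasing across iterations", {
  set.seed(9)
  for (i in 1:3) {
    im <- make_image(synth_image_spec(class = sample(c("benign", "aca"), 1),
                                      seed = 100 + i))
    cfg <- slic_config(M = 16, max_iter = 10, conv_tol = 0, enhance = FALSE)
    ctr <- grid_init_centers(im$image, 16)
    fit <- slic_iterate(im$image, ctr, cfg)
    expect_true(all(diff(fit$cost_trace) <= 1e-6))
  }
})

test_that("small-superpixel merging absorbs undersized components", {
  # no-op when nothing is undersized
  lm <- matrix(rep(0:1, each = 8), 4, 4)
  m <- merge_small_superpixels(lm, min_size = 4)
  expect_equal(m$n_segments, 2)
  expect_equal(sort(unique(as.vector(m$labels))), 0:1)

  # a single isolated pixel is absorbed into its surrounding segment
  lm2 <- matrix(0L, 5, 5); lm2[3, 3] <- 7L
  m2 <- merge_small_superpixels(lm2, min_size = 2)
  expect_equal(m2$n_segments, 1)
  expect_true(all(m2$labels == 0))

  # undersized middle strip merges into the longer-boundary neighbor
  lm3 <- matrix(2L, 6, 6)
  lm3[, 1:3] <- 0L          # label 0: columns 1-3
  lm3[1:2, 4] <- 1L         # label 1: 2 pixels touching 0 (2 edges) and 2 (3 edges)
  m3 <- merge_small_superpixels(lm3, min_size = 3)
  # boundary with label 2 is longer (3 shared edges vs 2), so 1 joins 2
  expect_equal(m3$n_segments, 2)
  joined <- m3$labels[1, 4]
  expect_equal(m3$labels[1, 5], joined)   # ended up with the right-hand segment
  expect_false(m3$labels[1, 3] == joined)
})

test_that("segmentation partitions the image deterministically", {
  im <- make_image(synth_image_spec(class = "aca", seed = 21))
  cfg <- slic_config(M = 16)
  seg1 <- slic_segment(im$image, cfg)
  seg2 <- slic_segment(im$image, cfg)
  expect_identical(seg1$labels, seg2$labels)

  labs <- as.vector(seg1$labels)
  expect_setequal(unique(labs), 0:(seg1$n_segments - 1))
  expect_equal(length(labs), 64 * 64)

  # superpixels are intensity-coherent: within-segment variance below global
  wv <- tapply(as.vector(im$image), labs, stats::var)
  expect_lt(mean(wv, na.rm = TRUE), stats::var(as.vector(im$image)))

  const <- matrix(100, 64, 64)
  seg_c <- slic_segment(const, slic_config(M = 16))
  expect_equal(seg_c$n_segments, 16)
  expect_true(max(table(as.vector(seg_c$labels))) <= 2 * min(table(as.vector(seg_c$labels))))
})

test_that("with alpha near zero the segmentation is a spatial Voronoi of the seeds", {
  im <- make_image(synth_image_spec(class = "benign", seed = 5))
  cfg <- slic_config(M = 16, alpha = 1e-12, max_iter = 1, enhance = FALSE)
  ctr <- grid_init_centers(im$image, 16)
  fit <- slic_iterate(im$image, ctr, cfg)
  for (p in sample(64 * 64, 100)) {
    y <- (p - 1) %% 64; x <- (p - 1) %/% 64
    d2 <- sort((ctr$x - x)^2 + (ctr$y - y)^2)
    if (d2[2] - d2[1] < 1e-6) next       # exact spatial ties are arbitrary
    d2 <- (ctr$x - x)^2 + (ctr$y - y)^2
    expect_equal(fit$labels[y + 1, x + 1], ctr$label[which.min(d2)])
  }
})

test_that("the ROI mask selects dark nuclei-dense superpixels", {
  im <- make_image(synth_image_spec(class = "aca", seed = 12))
  seg <- slic_segment(im$image, slic_config(M = 48, k_thresholds = 1))
  roi <- roi_mask(seg)
  # the ROI should overlap the true nucleus mask far better than chance
  overlap <- sum(roi & im$mask) / sum(im$mask)
  expect_gt(overlap, 0.6)
  expect_lt(mean(roi), 0.6)
})
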