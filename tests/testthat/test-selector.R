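# PSO and RDO optimizer primitives, the mask decoding, and the wrapper.

test_that("inertia weight decays linearly between its endpoints", {
  cfg <- pso_config(w_min = 0.45, w_max = 0.9, k_max = 100)
  expect_equal(inertia_weight(0, cfg), 0.9)
  expect_equal(inertia_weight(100, cfg), 0.45)
  expect_equal(inertia_weight(50, cfg), 0.675)
  expect_error(inertia_weight(101, cfg), "k must lie")
})

test_that("PSO solves the sphere, is seed-reproducible, and keeps a monotone trace", {
  bench <- benchmark_fitness("sphere", dim = 5)
  cfg <- pso_config(n_particles = 30, k_max = 200, seed = 7)
  res <- pso_optimize(bench$f, 5, cfg, bench$lower, bench$upper)
  expect_true(all(abs(res$best_position) < 1e-2))
  expect_true(all(diff(res$trace) >= 0))

  res2 <- pso_optimize(bench$f, 5, cfg, bench$lower, bench$upper)
  expect_identical(res$trace, res2$trace)

  flat <- pso_optimize(function(x) 42, 3, pso_config(n_particles = 5, k_max = 3),
                       -1, 1)
  expect_equal(flat$best_score, 42)
  expect_error(pso_optimize(function(x) NaN, 2, pso_config(k_max = 2), -1, 1),
               "non-finite")
})

test_that("PSO with zero acceleration is inertia-damped drift that contracts", {
  f <- function(x) -sum(x^2)
  cfg <- pso_config(n_particles = 10, k_max = 60, c1 = 0, c2 = 0,
                    w_min = 0.5, w_max = 0.5, seed = 3)
  res <- pso_optimize(f, 4, cfg, -1, 1)
  # velocities shrink geometrically (|w| < 1), so late gbest improvements stop
  late <- res$trace[40:60]
  expect_lt(max(late) - min(late), 1e-4)
})

test_that("positions decode to masks with the argmax rescue", {
  expect_true(all(position_to_mask(rep(10, 5))))
  expect_equal(sum(position_to_mask(rep(-10, 5))), 1)
  expect_equal(position_to_mask(c(-1, 0.2, 3)), c(FALSE, TRUE, TRUE))
  expect_error(position_to_mask(c(1, NA)), "finite")
})

test_that("roaring follows the printed move and accepts greedily", {
  f <- function(x) -sum(x^2)
  # zero-width bounds: the position cannot move
  r0 <- roaring_update(c(0, 0), 0, f, 0, 0)
  expect_equal(r0$position, c(0, 0))

  # fixed draws: old + a1 * ((UL - LL) * a2 + LL), sign from a3
  r1 <- roaring_update(c(0.1, 0.1), f(c(0.1, 0.1)), function(x) sum(x), 0, 2,
                       draws = list(a1 = 1, a2 = 1, a3 = 0.9))
  expect_equal(r1$position, c(2, 2))      # 0.1 + 2, clipped to UL = 2

  # a worse candidate is rejected
  r2 <- roaring_update(c(0, 0), 0, f, -2, 2, draws = list(a1 = 1, a2 = 1, a3 = 0.9))
  expect_equal(r2$position, c(0, 0))
  expect_equal(r2$fitness, 0)
})

test_that("fights pick the best of commander, stag and the two midpoint moves", {
  f <- function(x) -sum((x - 1)^2)
  same <- fight_update(c(1, 1), f(c(1, 1)), c(1, 1), f(c(1, 1)), f, 1, 1)
  expect_equal(same$position, c(1, 1))

  fm <- function(x) -sum((x - 2)^2)       # midpoint is the optimum
  mid <- fight_update(c(0, 0), fm(c(0, 0)), c(4, 4), fm(c(4, 4)), fm, 0, 4,
                      draws = list(b1 = 0, b2 = 0.5))
  expect_equal(mid$position, c(2, 2))     # b1 = 0: both candidates at midpoint

  # direct substitution: mid = 2, shift = b1 * ((UL - LL) * b2 + LL) = 1,
  # so New1 = 3, New2 = 1; the fitness peaks at New1
  m <- fight_update(0, -9, 4, -1, function(x) -sum((x - 3)^2), -2, 6,
                    draws = list(b1 = 0.5, b2 = 0.5))
  expect_equal(m$position, 3)
})

test_that("harem allocation apportions hinds exactly", {
  expect_equal(harem_allocation(5, 58), 58L)
  expect_equal(harem_allocation(c(0.5, 0.3, 0.2), 58), c(29L, 17L, 12L))
  expect_equal(harem_allocation(c(2, 2), 58), c(29L, 29L))
  expect_equal(sum(harem_allocation(c(1, 1, 1), 58)), 58L)
  expect_equal(harem_allocation(c(0, 0), 10), c(5L, 5L))
  set.seed(2)
  for (i in 1:20) {
    fit <- runif(sample(2:6, 1))
    n <- sample(10:100, 1)
    expect_equal(sum(harem_allocation(fit, n)), n)
  }
})

test_that("offspring sit at the parent midpoint plus the bounded shift", {
  expect_equal(offspring_update(c(1, 3), c(3, 1), 2, 2), c(2, 2))  # zero width
  expect_equal(offspring_update(0, 2, 0, 4, draws = list(c = 0.25)), 2)
  set.seed(4)
  for (i in 1:200) {
    off <- offspring_update(runif(3, -1, 1), runif(3, -1, 1), -1, 1)
    expect_true(all(off >= -1 & off <= 1))
  }
})

test_that("RDO conserves the population, is reproducible, and loads published defaults", {
  cfg <- rdo_config()
  expect_equal(cfg$n_pop, 100L)
  expect_equal(cfg$n_males, 12L)
  expect_equal(cfg$alpha, 0.9)
  expect_equal(cfg$beta, 0.5)
  expect_equal(cfg$gamma, 0.6)
  expect_equal(c(cfg$roar_p, cfg$fight_p, cfg$mating_p), c(0.23, 0.47, 0.78))
  expect_error(rdo_config(n_pop = 5, n_males = 6), "exceed")

  bench <- benchmark_fitness("sphere", dim = 5)
  cfg <- rdo_config(max_iter = 20, seed = 11)
  res <- rdo_optimize(bench$f, 5, cfg, bench$lower, bench$upper)
  expect_true(all(res$pop_sizes == 100))
  expect_true(all(diff(res$trace) >= 0))
  res2 <- rdo_optimize(bench$f, 5, cfg, bench$lower, bench$upper)
  expect_identical(res$trace, res2$trace)
})

test_that("the wrapper keeps the only feature at d = 1 and has monotone traces", {
  lf <- blob_data(12, 1, shift = 2, seed = 5)
  sel <- select_features(lf$x, lf$y, "pso",
                         pso_config(n_particles = 10, k_max = 10, seed = 1))
  expect_true(sel$mask)
  expect_equal(sel$n_selected, 1L)

  lf2 <- blob_data(12, 6, shift = 2, seed = 6)
  for (m in c("pso", "rdo")) {
    cfg <- if (m == "pso") pso_config(n_particles = 15, k_max = 15, seed = 2)
           else rdo_config(n_pop = 15, n_males = 4, max_iter = 10, seed = 2)
    sel <- select_features(lf2$x, lf2$y, m, cfg)
    expect_true(all(diff(sel$trace) >= 0))
    expect_gte(sel$n_selected, 1L)
  }
})

test_that("pure-noise features yield no false certainty", {
  set.seed(13)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- rep(c(0L, 1L), each = 20)
  sel <- select_features(X, y, "pso",
                         pso_config(n_particles = 20, k_max = 20, seed = 3))
  # the best achievable fitness stays near chance level
  expect_lt(sel$score, 0.75)
})
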