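# Selective feature pooling: PSO and red-deer (RDO) metaheuristic engines
# searching a continuous position space, a sigmoid decoding of positions
# into feature-subset masks, the wrapper fitness, and entropy diagnostics.
#
# Both optimizers MAXIMIZE the fitness, keep an elitist best-so-far, and
# are fully reproducible from the seed in their configuration.

#' PSO configuration
#'
#' @param n_particles swarm size.
#' @param k_max iteration count (>= 1).
#' @param w_min,w_max inertia-weight decay endpoints (0 < w_min <= w_max);
#'   the weight decays linearly from `w_max` at iteration 0 to `w_min` at
#'   `k_max`.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param r_mode `"fixed"` uses the constant `r_value` for both stochastic
#'   factors every step (the published operating mode); `"random"` draws
#'   them uniformly per particle and step (textbook PSO).
#' @param r_value the fixed stochastic factor (default 0.85).
#' @param v_max velocity clamp per coordinate (NULL = half the box width).
#' @param seed RNG seed.
#' @return a `pso_config` list.
#' @export
pso_config <- function(n_particles = 30L, k_max = 100L, w_min = 0.45,
                       w_max = 0.9, c1 = 1.5, c2 = 1.5,
                       r_mode = c("fixed", "random"), r_value = 0.85,
                       v_max = NULL, seed = 1L) {
  r_mode <- match.arg(r_mode)
  if (w_min <= 0 || w_min > w_max) stop("require 0 < w_min <= w_max")
  if (k_max < 1L) stop("k_max must be >= 1")
  structure(list(n_particles = as.integer(n_particles), k_max = as.integer(k_max),
                 w_min = w_min, w_max = w_max, c1 = c1, c2 = c2,
                 r_mode = r_mode, r_value = r_value, v_max = v_max,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Linearly decaying inertia weight
#'
#' `w(k) = w_max - (w_max - w_min) * k / k_max`: `w_max` at the first
#' iteration, `w_min` at the last.
#'
#' @param k iteration index (0 <= k <= k_max).
#' @param cfg a [pso_config()].
#' @return the inertia weight.
#' @export
inertia_weight <- function(k, cfg) {
  if (k < 0 || k > cfg$k_max) stop("k must lie in [0, k_max]")
  cfg$w_max - (cfg$w_max - cfg$w_min) * k / cfg$k_max
}

#' Particle swarm optimization
#'
#' Velocity update `q <- w*q + c1*r1*(pbest - p) + c2*r2*(gbest - p)`,
#' position update `p <- p + q`, with per-coordinate velocity clamping and
#' positions clipped to the search box. The global best is elitist, so its
#' score trace is non-decreasing.
#'
#' @param f fitness function: numeric vector -> finite scalar (maximized).
#' @param dim search dimension.
#' @param cfg a [pso_config()].
#' @param lower,upper search box bounds (scalars or length-`dim` vectors).
#' @return list with `best_position`, `best_score`, `trace` (gbest score
#'   per iteration).
#' @export
pso_optimize <- function(f, dim, cfg = pso_config(), lower = -1, upper = 1) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  v_max <- if (is.null(cfg$v_max)) (upper - lower) / 2 else rep_len(cfg$v_max, dim)
  with_seed(cfg$seed, {
    pos <- matrix(stats::runif(cfg$n_particles * dim, lower, upper),
                  cfg$n_particles, dim, byrow = TRUE)
    vel <- matrix(stats::runif(cfg$n_particles * dim, -v_max, v_max),
                  cfg$n_particles, dim, byrow = TRUE)
    fit <- apply(pos, 1, f)
    if (any(!is.finite(fit))) stop("non-finite fitness at initialization")
    pbest <- pos; pbest_fit <- fit
    g <- which.max(fit)
    gbest <- pos[g, ]; gbest_fit <- fit[g]
    trace <- numeric(cfg$k_max)
    for (k in 0:(cfg$k_max - 1L)) {
      w <- inertia_weight(k, cfg)
      if (cfg$r_mode == "fixed") {
        r1 <- cfg$r_value; r2 <- cfg$r_value
      } else {
        r1 <- matrix(stats::runif(cfg$n_particles * dim), cfg$n_particles, dim)
        r2 <- matrix(stats::runif(cfg$n_particles * dim), cfg$n_particles, dim)
      }
      vel <- w * vel + cfg$c1 * r1 * (pbest - pos) +
        cfg$c2 * r2 * (matrix(gbest, cfg$n_particles, dim, byrow = TRUE) - pos)
      vel <- t(pmin(pmax(t(vel), -v_max), v_max))
      pos <- pos + vel
      pos <- t(pmin(pmax(t(pos), lower), upper))
      fit <- apply(pos, 1, f)
      if (any(!is.finite(fit))) stop("non-finite fitness at iteration ", k)
      improved <- fit > pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      g <- which.max(pbest_fit)
      if (pbest_fit[g] > gbest_fit) {
        gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
      }
      trace[k + 1L] <- gbest_fit
    }
    list(best_position = gbest, best_score = gbest_fit, trace = trace)
  })
}

#' Decode a continuous position into a feature mask
#'
#' Feature i is kept when `sigmoid(p_i) > 0.5` (i.e. `p_i > 0`). If no
#' coordinate qualifies, the single highest-sigmoid feature is kept so the
#' mask is never empty.
#'
#' @param p finite numeric position vector.
#' @return logical keep vector of the same length.
#' @export
position_to_mask <- function(p) {
  if (any(!is.finite(p))) stop("position must be finite")
  keep <- sigmoid(p) > 0.5
  if (!any(keep)) keep[which.max(p)] <- TRUE
  keep
}

#' RDO configuration
#'
#' Defaults follow the published parameter table: population 100, 12 male
#' red deer, alpha 0.9 (within-harem mating fraction), beta 0.5
#' (cross-harem mating fraction), gamma 0.6 (commander share of males),
#' and the roar/fight/mating event probabilities 0.23 / 0.47 / 0.78. The
#' number of hinds is `n_pop - n_males` so the population is conserved
#' (an `n_hinds` override is accepted for reproducing legacy settings).
#'
#' @param n_pop population size.
#' @param n_males number of male red deer (`< n_pop`).
#' @param alpha,beta,gamma,roar_p,fight_p,mating_p rates in \[0, 1\].
#' @param max_iter generation count.
#' @param patience stop when the best score has not improved for this many
#'   generations (Inf = run all generations).
#' @param time_cap_s optional wall-clock cap in seconds (NULL = off).
#' @param n_hinds optional override of the hind count.
#' @param seed RNG seed.
#' @return an `rdo_config` list.
#' @export
rdo_config <- function(n_pop = 100L, n_males = 12L, alpha = 0.9, beta = 0.5,
                       gamma = 0.6, roar_p = 0.23, fight_p = 0.47,
                       mating_p = 0.78, max_iter = 50L, patience = Inf,
                       time_cap_s = NULL, n_hinds = NULL, seed = 1L) {
  if (n_males >= n_pop) stop("population must exceed the number of males")
  rates <- c(alpha, beta, gamma, roar_p, fight_p, mating_p)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(n_pop = as.integer(n_pop), n_males = as.integer(n_males),
                 alpha = alpha, beta = beta, gamma = gamma, roar_p = roar_p,
                 fight_p = fight_p, mating_p = mating_p,
                 max_iter = as.integer(max_iter), patience = patience,
                 time_cap_s = time_cap_s,
                 n_hinds = if (is.null(n_hinds)) NULL else as.integer(n_hinds),
                 seed = as.integer(seed)),
            class = "rdo_config")
}

#' Roaring update of a male red deer
#'
#' Proposes `old +/- a1 * ((UL - LL) * a2 + LL)` per coordinate (sign by
#' `a3 >= 0.5`), clips to the bounds, and keeps the proposal only if its
#' fitness improves (greedy acceptance).
#'
#' @param position,fitness current male state.
#' @param f fitness function.
#' @param lower,upper bounds.
#' @param draws optional list with fixed `a1`, `a2`, `a3` (each scalar or
#'   per-coordinate); by default drawn U(0, 1) per coordinate.
#' @return list with `position` and `fitness`.
#' @export
roaring_update <- function(position, fitness, f, lower, upper, draws = NULL) {
  d <- length(position)
  a1 <- if (is.null(draws)) stats::runif(d) else rep_len(draws$a1, d)
  a2 <- if (is.null(draws)) stats::runif(d) else rep_len(draws$a2, d)
  a3 <- if (is.null(draws)) stats::runif(d) else rep_len(draws$a3, d)
  step <- a1 * ((upper - lower) * a2 + lower)
  cand <- clip(position + ifelse(a3 >= 0.5, step, -step), lower, upper)
  cand_fit <- f(cand)
  if (cand_fit > fitness) list(position = cand, fitness = cand_fit)
  else list(position = position, fitness = fitness)
}

#' Fight between a commander and a stag
#'
#' Two candidates around the midpoint,
#' `(Com + Stag)/2 +/- b1 * ((UL - LL) * b2 + LL)`, are evaluated and the
#' best of {commander, stag, candidate 1, candidate 2} becomes the new
#' commander.
#'
#' @param com,com_fit commander position and fitness.
#' @param stag,stag_fit stag position and fitness.
#' @param f fitness function.
#' @param lower,upper bounds.
#' @param draws optional list with fixed `b1`, `b2`.
#' @return list with `position` and `fitness` of the winning commander.
#' @export
fight_update <- function(com, com_fit, stag, stag_fit, f, lower, upper,
                         draws = NULL) {
  d <- length(com)
  b1 <- if (is.null(draws)) stats::runif(d) else rep_len(draws$b1, d)
  b2 <- if (is.null(draws)) stats::runif(d) else rep_len(draws$b2, d)
  shift <- b1 * ((upper - lower) * b2 + lower)
  mid <- (com + stag) / 2
  new1 <- clip(mid + shift, lower, upper)
  new2 <- clip(mid - shift, lower, upper)
  cand <- list(com, stag, new1, new2)
  fits <- c(com_fit, stag_fit, f(new1), f(new2))
  j <- which.max(fits)
  list(position = cand[[j]], fitness = fits[j])
}

#' Harem sizes from commander fitness shares
#'
#' Hinds are apportioned proportionally to the commanders' (non-negative)
#' fitness values, `round(P_n * N_hind)`, with a largest-remainder
#' correction so the counts sum exactly to `n_hinds`. All-zero fitness
#' splits the hinds as evenly as possible.
#'
#' @param fitnesses non-negative commander fitness vector.
#' @param n_hinds total number of hinds to allocate.
#' @return integer vector of harem sizes summing to `n_hinds`.
#' @export
harem_allocation <- function(fitnesses, n_hinds) {
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  m <- length(fitnesses)
  if (sum(fitnesses) == 0) {
    base <- rep(n_hinds %/% m, m)
    extra <- n_hinds - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    return(as.integer(base))
  }
  share <- fitnesses / sum(fitnesses)
  counts <- round(share * n_hinds)
  diff <- n_hinds - sum(counts)
  if (diff != 0) {
    rem <- share * n_hinds - counts
    ord <- order(if (diff > 0) -rem else rem)
    for (i in seq_len(abs(diff))) {
      j <- ord[i]
      counts[j] <- counts[j] + sign(diff)
    }
  }
  as.integer(counts)
}

#' Offspring of a mating pair
#'
#' `(A + B)/2 + (UL - LL) * c` per coordinate with `c ~ U(0, 1)`, clipped
#' to the bounds.
#'
#' @param parent_a,parent_b parent positions.
#' @param lower,upper bounds.
#' @param draws optional list with a fixed `c`.
#' @return offspring position.
#' @export
offspring_update <- function(parent_a, parent_b, lower, upper, draws = NULL) {
  d <- length(parent_a)
  cc <- if (is.null(draws)) stats::runif(d) else rep_len(draws$c, d)
  clip((parent_a + parent_b) / 2 + (upper - lower) * cc, lower, upper)
}

#' Red deer optimization
#'
#' Generational loop: the population is ranked and the top `n_males`
#' become males (a `gamma` share of them commanders, the rest stags); each
#' male roars with probability `roar_p` (greedy position update); each
#' commander fights a random stag with probability `fight_p`; hinds are
#' apportioned into harems by commander fitness; commanders mate with an
#' `alpha` fraction of their own harem and a `beta` fraction of one other
#' harem, stags with their nearest hind, each eligible pair mating with
#' probability `mating_p`; the next generation keeps the males and fills
#' back to `n_pop` with the fittest of hinds plus offspring. The best-ever
#' solution is elitist.
#'
#' @param f fitness function: numeric vector -> finite scalar (maximized).
#' @param dim search dimension.
#' @param cfg an [rdo_config()].
#' @param lower,upper search box bounds (scalars or length-`dim` vectors).
#' @return list with `best_position`, `best_score`, `trace` (best score per
#'   generation), `pop_sizes` (population size after every generation).
#' @export
rdo_optimize <- function(f, dim, cfg = rdo_config(), lower = -1, upper = 1) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  n_pop <- cfg$n_pop; n_males <- cfg$n_males
  n_hinds <- if (is.null(cfg$n_hinds)) n_pop - n_males else cfg$n_hinds
  with_seed(cfg$seed, {
    pop <- matrix(stats::runif(n_pop * dim, lower, upper), n_pop, dim, byrow = TRUE)
    fit <- apply(pop, 1, f)
    if (any(!is.finite(fit))) stop("non-finite fitness at initialization")
    best_idx <- which.max(fit)
    best_pos <- pop[best_idx, ]; best_fit <- fit[best_idx]
    trace <- numeric(0); pop_sizes <- integer(0)
    stall <- 0L
    t0 <- Sys.time()
    for (gen in seq_len(cfg$max_iter)) {
      ord <- order(fit, decreasing = TRUE)
      pop <- pop[ord, , drop = FALSE]; fit <- fit[ord]
      males <- seq_len(n_males)
      n_com <- max(1L, round(cfg$gamma * n_males))
      # roaring (greedy, gated per male)
      for (i in males) {
        if (stats::runif(1) < cfg$roar_p) {
          upd <- roaring_update(pop[i, ], fit[i], f, lower, upper)
          pop[i, ] <- upd$position; fit[i] <- upd$fitness
        }
      }
      # re-rank males so improved roarers can become commanders
      mord <- order(fit[males], decreasing = TRUE)
      pop[males, ] <- pop[males, , drop = FALSE][mord, , drop = FALSE]
      fit[males] <- fit[males][mord]
      commanders <- seq_len(n_com)
      stags <- setdiff(males, commanders)
      # fights
      for (i in commanders) {
        if (length(stags) > 0L && stats::runif(1) < cfg$fight_p) {
          s <- if (length(stags) == 1L) stags else sample(stags, 1L)
          upd <- fight_update(pop[i, ], fit[i], pop[s, ], fit[s], f, lower, upper)
          pop[i, ] <- upd$position; fit[i] <- upd$fitness
        }
      }
      # harems over the hind pool (the ranked remainder of the population)
      hind_idx <- (n_males + 1L):n_pop
      hind_pool <- hind_idx[seq_len(min(n_hinds, length(hind_idx)))]
      com_fit <- fit[commanders]
      shifted <- com_fit - min(com_fit) + 1e-12
      harems <- harem_allocation(shifted, length(hind_pool))
      assignment <- rep(commanders, times = harems)
      offspring <- list()
      mate <- function(a, b) {
        if (stats::runif(1) < cfg$mating_p) {
          offspring[[length(offspring) + 1L]] <<- offspring_update(a, b, lower, upper)
        }
      }
      pos <- 0L
      for (ci in seq_along(commanders)) {
        h <- hind_pool[assignment == commanders[ci]]
        pos <- pos + harems[ci]
        if (length(h) > 0L) {
          n_own <- round(cfg$alpha * length(h))
          own <- if (n_own > 0L) sample(h, n_own) else integer(0)
          for (hh in own) mate(pop[commanders[ci], ], pop[hh, ])
        }
        others <- setdiff(hind_pool, h)
        if (length(others) > 0L) {
          n_other <- round(cfg$beta * length(others) / max(1L, length(commanders)))
          oth <- if (n_other > 0L) sample(others, min(n_other, length(others))) else integer(0)
          for (hh in oth) mate(pop[commanders[ci], ], pop[hh, ])
        }
      }
      # stags mate with their nearest hind
      for (s in stags) {
        if (length(hind_pool) == 0L) break
        dists <- rowSums((pop[hind_pool, , drop = FALSE] -
                            matrix(pop[s, ], length(hind_pool), dim, byrow = TRUE))^2)
        mate(pop[s, ], pop[hind_pool[which.min(dists)], ])
      }
      # next generation: keep males, refill from hinds + offspring by fitness
      off_mat <- if (length(offspring)) do.call(rbind, offspring) else NULL
      off_fit <- if (length(offspring)) apply(off_mat, 1, f) else numeric(0)
      pool_pos <- rbind(pop[-males, , drop = FALSE], off_mat)
      pool_fit <- c(fit[-males], off_fit)
      keep <- order(pool_fit, decreasing = TRUE)[seq_len(n_pop - n_males)]
      pop <- rbind(pop[males, , drop = FALSE], pool_pos[keep, , drop = FALSE])
      fit <- c(fit[males], pool_fit[keep])
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best_fit <- fit[gen_best]; best_pos <- pop[gen_best, ]; stall <- 0L
      } else stall <- stall + 1L
      trace <- c(trace, best_fit)
      pop_sizes <- c(pop_sizes, nrow(pop))
      if (stall >= cfg$patience) break
      if (!is.null(cfg$time_cap_s) &&
          as.numeric(difftime(Sys.time(), t0, units = "secs")) > cfg$time_cap_s) break
    }
    list(best_position = best_pos, best_score = best_fit, trace = trace,
         pop_sizes = pop_sizes)
  })
}

#' Wrapper feature selection
#'
#' Runs PSO or RDO over the sigmoid-logit mask encoding. The fitness of a
#' candidate position is the mean stratified 3-fold accuracy of a KNN
#' (k = 5) classifier on the masked features minus the sparsity penalty
#' `lambda_s * n_selected / d`. The folds are fixed once per call, so the
#' fitness is deterministic and both optimizers' traces are monotone.
#' The search box is the narrow logit interval \[-0.5, 0.5\] around the
#' keep/drop boundary, so single-feature flips stay within reach of one
#' velocity step; the default configurations are sized for this search
#' (PSO additionally defaults to per-step random stochastic factors here,
#' which explore the high-dimensional mask space better than the fixed
#' published factor).
#'
#' @param features numeric matrix (rows = samples).
#' @param labels 0/1 vector with both classes present.
#' @param method `"pso"` or `"rdo"`.
#' @param cfg a [pso_config()] or [rdo_config()] matching `method`.
#' @param lambda_s sparsity penalty weight.
#' @param eval_seed seed for the internal fold plan.
#' @return list with `mask` (logical), `n_selected`, `score`, `trace`.
#' @export
select_features <- function(features, labels, method = c("pso", "rdo"),
                            cfg = NULL, lambda_s = 0.01, eval_seed = 1L) {
  method <- match.arg(method)
  labels <- .check_labels(labels, nrow(features))
  d <- ncol(features)
  if (is.null(cfg)) {
    cfg <- if (method == "pso") {
      pso_config(n_particles = 60L, k_max = 150L, r_mode = "random", v_max = 0.1)
    } else {
      rdo_config(n_pop = 40L, n_males = 8L, max_iter = 40L)
    }
  }
  folds <- kfold_plan(labels, K = min(3L, min(table(labels))), seed = eval_seed)$fold
  fitness <- function(p) {
    mask <- position_to_mask(p)
    acc <- .knn_cv_score(features[, mask, drop = FALSE], labels, folds)
    acc - lambda_s * sum(mask) / d
  }
  res <- if (method == "pso") {
    pso_optimize(fitness, dim = d, cfg = cfg, lower = -0.5, upper = 0.5)
  } else {
    rdo_optimize(fitness, dim = d, cfg = cfg, lower = -0.5, upper = 0.5)
  }
  mask <- position_to_mask(res$best_position)
  list(mask = mask, n_selected = sum(mask), score = res$best_score,
       trace = res$trace, method = method)
}
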