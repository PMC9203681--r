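sphere <- benchmark_function("sphere")

test_that("initialisation respects bounds, seeds, and degenerate ranges", {
  cfg <- hdpab_config(NP = 10, dims = 3, bounds = c(0, 1), seed = 5)
  st <- initialize_population(cfg, sphere$fn)
  expect_true(all(st$positions >= 0 & st$positions <= 1))
  expect_equal(st$velocities, matrix(0, 10, 3))
  expect_equal(st$elite_val, min(st$fitness))
  st2 <- initialize_population(cfg, sphere$fn)
  expect_identical(st, st2)

  b <- rbind(c(0, 2, 2), c(1, 2, 5))    # dim 2 degenerate
  cfg3 <- hdpab_config(NP = 6, dims = 3, bounds = b, seed = 1)
  st3 <- initialize_population(cfg3, sphere$fn)
  expect_true(all(st3$positions[, 2] == 2))

  expect_error(hdpab_config(NP = 3, dims = 2, bounds = c(0, 1)), "at least 4")
})

test_that("DE mutation/crossover boundaries behave as written", {
  # mutant arithmetic: A_x + G (A_z - A_w)
  expect_equal(c(1, 1) + 0.5 * (c(2, 0) - c(0, 2)), c(2, 0))

  cfg <- hdpab_config(NP = 8, dims = 4, bounds = c(-2, 2), seed = 9)
  st <- initialize_population(cfg, sphere$fn)
  # greedy selection never worsens any member
  for (rep in 1:5) {
    before <- st$fitness
    st <- de_step(st, G = 0.7, CR = 0.9, sphere$fn)
    expect_true(all(st$fitness <= before + 1e-15))
    expect_true(all(st$positions >= -2 & st$positions <= 2))
  }
  # CR = 0 (no forced crossover index): trial equals parent, state fixed
  st0 <- initialize_population(cfg, sphere$fn)
  st0b <- de_step(st0, G = 0.7, CR = 0, sphere$fn)
  expect_equal(st0b$positions, st0$positions)
  expect_equal(st0b$fitness, st0$fitness)
  # identical population: zero difference vectors, no change possible
  sti <- st0
  sti$positions <- matrix(1, 8, 4)
  sti$fitness <- rep(sphere$fn(rep(1, 4)), 8)
  stib <- de_step(sti, G = 0.5, CR = 1, sphere$fn)
  expect_equal(stib$positions, sti$positions)
})

test_that("PSO update follows the printed deterministic recursion", {
  cfg <- hdpab_config(NP = 5, dims = 2, bounds = c(-10, 10), seed = 3)
  st <- initialize_population(cfg, sphere$fn)
  st$velocities <- matrix(1, 5, 2)
  # w1 = w2 = 0, q = 1: velocities unchanged, pure translation
  st1 <- pso_step(st, 1, 0, 0, sphere$fn)
  expect_equal(st1$velocities, st$velocities)
  expect_equal(st1$positions, st$positions + 1)
  # particle sitting at both bests with q = 0.5: velocity halves per call
  stq <- st
  stq$positions <- matrix(0, 5, 2)
  stq$pbest_pos <- stq$positions
  stq$gbest_pos <- c(0, 0)
  stq$velocities <- matrix(2, 5, 2)
  stq1 <- pso_step(stq, 0.5, 1.2, 1.4, sphere$fn)
  # after moving, position != best, but first velocity update is q * v
  expect_equal(stq1$velocities[1, ], c(1, 1))
  # equilibrium: at gbest with zero velocity -> stationary
  ste <- stq
  ste$velocities <- matrix(0, 5, 2)
  ste1 <- pso_step(ste, 0.7, 1.5, 1.5, sphere$fn)
  expect_equal(ste1$positions, ste$positions)
})

test_that("scout phase re-seeds only exhausted members and spares the elite", {
  cfg <- hdpab_config(NP = 6, dims = 3, bounds = c(-1, 1), seed = 11)
  st <- initialize_population(cfg, sphere$fn)
  st_noop <- abc_scout_step(st, limit = 5, sphere$fn)
  expect_identical(st_noop, st)     # no counter at limit -> unchanged
  st$trial <- c(5L, 0L, 5L, 0L, 0L, 0L)
  elite_before <- st$elite_val
  st2 <- abc_scout_step(st, limit = 5, sphere$fn)
  expect_equal(st2$trial[c(1, 3)], c(0L, 0L))
  expect_false(isTRUE(all.equal(st2$positions[1, ], st$positions[1, ])))
  expect_equal(st2$positions[2, ], st$positions[2, ])
  expect_lte(st2$elite_val, elite_before)
  expect_true(all(st2$positions >= -1 & st2$positions <= 1))
})

test_that("the full loop is elitist, bounded, seeded, and converges on sphere", {
  cfg <- hdpab_config(NP = 30, dims = 10, bounds = c(-5, 5), max_iter = 200,
                      seed = 1)
  res <- hdpab_optimize(sphere$fn, cfg)
  expect_true(all(diff(res$history) <= 0))          # elite never worsens
  expect_lt(res$best_value, 1e-2)
  expect_true(all(res$state$positions >= -5 & res$state$positions <= 5))
  expect_length(res$history, 201L)
  # bit-stable trajectory under the same seed
  res2 <- hdpab_optimize(sphere$fn, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(res$best_position, res2$best_position)
  # max_iter = 0 returns the best of the initial population
  cfg0 <- hdpab_config(NP = 10, dims = 4, bounds = c(-5, 5), max_iter = 0,
                       seed = 2)
  res0 <- hdpab_optimize(sphere$fn, cfg0)
  st0 <- initialize_population(cfg0, sphere$fn)
  expect_equal(res0$best_value, min(st0$fitness))
})

test_that("HDPAB beats equal-budget random search on the sphere", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- hdpab_config(NP = 20, dims = 8, bounds = c(-5, 5), max_iter = 60,
                        seed = s)
    res <- hdpab_optimize(sphere$fn, cfg)
    rs <- random_search(sphere$fn, cfg$bounds, res$state$n_eval,
                        seed = 20000 + s)
    wins <- wins + (res$best_value < rs)
  }
  expect_gte(wins, 9L)
})

test_that("rastrigin run reaches a near-optimal basin", {
  ras <- benchmark_function("rastrigin")
  cfg <- hdpab_config(NP = 40, dims = 5, bounds = c(-5.12, 5.12),
                      max_iter = 300, seed = 1)
  res <- hdpab_optimize(ras$fn, cfg)
  expect_lt(res$best_value, 5)
  rs <- random_search(ras$fn, cfg$bounds, res$state$n_eval, seed = 77)
  expect_gt(rs, res$best_value)
})

test_that("positions decode to masks with the empty-mask fallback", {
  expect_equal(position_to_mask(rep(10, 4)), rep(TRUE, 4))
  m <- position_to_mask(c(-10, -12, -9, -11))
  expect_equal(which(m), 3L)           # highest sigmoid wins the fallback
  expect_equal(sum(m), 1L)
  # exact threshold is excluded (strict inequality)
  expect_false(position_to_mask(c(0, 3))[1])
})

test_that("subset fitness rewards separating features and penalises size", {
  sep <- make_separable_features(n_per_class = 30, p = 5,
                                 informative = 1L, delta = 6, seed = 13)
  m1 <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  f1 <- subset_fitness(m1, sep$x, sep$y, lambda = 0)
  expect_lt(f1, 0.02)
  # shuffled labels: near-chance fitness
  set.seed(14)
  f_null <- subset_fitness(m1, sep$x, sample(sep$y), lambda = 0)
  expect_gt(f_null, 0.3)
  expect_lt(f_null, 0.7)
  # a large penalty makes the full mask worse than the sparse one
  f_full <- subset_fitness(rep(TRUE, 5), sep$x, sep$y, lambda = 1)
  f_sparse <- subset_fitness(m1, sep$x, sep$y, lambda = 1)
  expect_gt(f_full, f_sparse)
  expect_error(subset_fitness(m1, sep$x, rep("a", 60)), "two classes")
})

test_that("the selection wrapper finds the informative features", {
  sep <- make_separable_features(n_per_class = 30, p = 6,
                                 informative = c(2L, 5L), delta = 4, seed = 15)
  sel <- select_features_hdpab(sep$x, sep$y, NP = 10, max_iter = 10, seed = 3)
  expect_true(any(sel$mask[c(2, 5)]))
  expect_true(all(diff(sel$history) <= 0))
})
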