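test_that("mutation keeps genomes valid and respects the weight alphabet", {
  set.seed(41)
  env <- scaled_env()
  cfg <- tiny_config(env)
  g <- random_genome_for(env)
  for (i in 1:300) {
    g <- mutate(g, cfg)
  }
  expect_silent(validate_genome(g))
  w <- unlist(lapply(g$weights, as.vector))
  expect_true(all(w %in% -2:2))
})

test_that("out-of-range mutations are ignored and steps skip zero", {
  env <- scaled_env()
  # force weight mutation with probability 1: single connection, rate 2/1
  cfg <- tiny_config(env, mutation = list(add = 0, remove = 0,
                                          threshold = 0, weight = 2))
  g <- empty_genome(env)
  g$weights[[1]][1, 1] <- 2L
  set.seed(42)
  seen <- integer(0)
  for (i in 1:100) {
    g2 <- mutate(g, cfg)
    seen <- c(seen, g2$weights[[1]][1, 1])
  }
  # from +2: increments are ignored (stay 2), decrements go to +1
  expect_setequal(unique(seen), c(2L, 1L))
  # from -1: steps skip 0, so results are -2 or +1
  g$weights[[1]][1, 1] <- -1L
  seen <- integer(0)
  for (i in 1:200) seen <- c(seen, mutate(g, cfg)$weights[[1]][1, 1])
  expect_setequal(unique(seen), c(-2L, 1L))
  # remove on a connectionless genome is a no-op
  cfg2 <- tiny_config(env, mutation = list(add = 0, remove = 1,
                                           threshold = 0, weight = 0))
  g0 <- empty_genome(env)
  expect_identical(mutate(g0, cfg2)$weights, g0$weights)
})

test_that("empirical mutation-event rates match the configured ones", {
  set.seed(43)
  env <- scaled_env()
  cfg <- tiny_config(env)
  g <- random_genome_for(env)
  n_calls <- 20000L
  ev <- matrix(0, n_calls, 4)
  for (i in seq_len(n_calls)) {
    ev[i, ] <- attr(mutate(g, cfg), "events")
  }
  expect_equal(mean(ev[, 1]), 0.20, tolerance = 0.05)   # add
  expect_equal(mean(ev[, 2]), 0.20, tolerance = 0.05)   # remove
  # threshold attempts per node per call
  expect_equal(mean(ev[, 3]) / sum(env$layer_sizes), 1 / 24,
               tolerance = 0.05)
  # weight attempts per call: n * (2 / n) = 2 expected
  expect_equal(mean(ev[, 4]), 2, tolerance = 0.05)
})

test_that("real-valued mode perturbs weights within [-2, 2]", {
  set.seed(44)
  env <- scaled_env()
  cfg <- tiny_config(env, weight_mode = "real")
  g <- integer_genome <- random_genome_for(env)
  g <- modcost:::integer_to_real_genome(g)
  for (i in 1:200) g <- mutate(g, cfg)
  w <- unlist(lapply(g$weights, as.vector))
  expect_true(all(abs(w) <= 2))
  expect_true(any(w != round(w)))  # genuinely real-valued by now
  expect_silent(validate_genome(g))
})

test_that("stochastic dominance reduces to the documented cases", {
  # p = 1: plain Pareto dominance, no randomness consulted
  set.seed(45)
  expect_true(stochastic_dominates(c(1, 2), c(0, 1), p = 1))
  expect_false(stochastic_dominates(c(1, 0), c(0, 1), p = 1))
  expect_false(stochastic_dominates(c(1, 1), c(1, 1), p = 1))
  # p = 0: only the first objective matters
  expect_true(stochastic_dominates(c(1, -99), c(0.5, 1), p = 0))
  expect_false(stochastic_dominates(c(0.5, 99), c(1, 0), p = 0))
  # identical vectors never dominate each other at any p
  for (p in c(0, 0.25, 1))
    expect_false(stochastic_dominates(c(0.5, 3), c(0.5, 3), p))
  # single objective: strict improvement decides
  expect_true(stochastic_dominates(0.7, 0.5))
  expect_false(stochastic_dominates(0.5, 0.5))
})

test_that("non-dominated sorting peels layers correctly at p extremes", {
  set.seed(46)
  # strict chain on both objectives: one individual per layer
  ch <- chain_objectives(6)
  r <- stochastic_nondominated_sort(ch$perf, ch$sec, p = 1)
  expect_equal(r, 6:1)
  # mutually non-dominating set: a single layer
  perf <- c(1, 2, 3, 4)
  sec <- c(4, 3, 2, 1)
  expect_equal(stochastic_nondominated_sort(perf, sec, p = 1),
               rep(1L, 4))
  # p = 0: layers ordered purely by performance, ties share a layer
  perf <- c(0.2, 0.9, 0.5, 0.9, 0.2)
  sec <- runif(5)
  r0 <- stochastic_nondominated_sort(perf, sec, p = 0)
  oracle <- as.integer(factor(-perf, levels = sort(unique(-perf))))
  expect_equal(r0, oracle)
})

test_that("crowding distance: boundaries infinite, middles normalized", {
  expect_identical(crowding_distance(cbind(0.5)), Inf)
  expect_identical(crowding_distance(cbind(c(0.1, 0.9))), c(Inf, Inf))
  d <- crowding_distance(cbind(c(0, 1, 2)))
  expect_identical(d[c(1, 3)], c(Inf, Inf))
  expect_equal(d[2], 1)
  d2 <- crowding_distance(cbind(c(0, 1, 2, 4)))
  expect_equal(d2[2:3], c(2 / 4, 3 / 4))
})

test_that("tournament selection prefers dominators, then rank, then crowding", {
  set.seed(47)
  # index 1 dominates index 2 on both objectives at p = 1; both
  # contestants are drawn at random, so 2 only wins the (2, 2) draws
  perf <- c(1, 0.5)
  sec <- c(2, 1)
  rank <- c(1L, 2L)
  crowd <- c(Inf, Inf)
  picks <- select_parents(perf, sec, rank, crowd, p = 1, k = 2000)
  expect_equal(mean(picks == 1L), 0.75, tolerance = 0.1)
  # non-dominating pair: crowding decides
  perf <- c(1, 0.5)
  sec <- c(1, 2)
  rank <- c(1L, 1L)
  crowd <- c(0.1, 5)
  picks <- select_parents(perf, sec, rank, crowd, p = 1, k = 500)
  drawn_pairs <- picks  # both indices occur; when both are drawn, 2 wins
  expect_true(mean(picks == 2L) > 0.5)
  # identical individuals: uniform choice
  picks <- select_parents(c(1, 1), c(1, 1), c(1L, 1L), c(Inf, Inf),
                          p = 1, k = 2000)
  expect_gt(mean(picks == 1L), 0.4)
  expect_lt(mean(picks == 1L), 0.6)
})

test_that("a generation preserves population size and stays elitist", {
  set.seed(48)
  env <- scaled_env()
  cfg <- evolution_config(env, "PCC_length", pop_size = 30,
                          generations = 5, seed = 1)
  genomes <- replicate(30, random_genome_for(env), simplify = FALSE)
  pop <- modcost:::evaluate_population(genomes, env, cfg)
  best <- max(pop$perf)
  for (g in 1:5) {
    pop <- evolve_generation(pop, env, cfg)
    expect_length(pop$genomes, 30L)
    expect_gte(max(pop$perf), best)   # best performance never decreases
    best <- max(pop$perf)
    expect_true(all(pop$perf >= 0 & pop$perf <= 1))
  }
})

test_that("PRO treatment draws a fresh random objective per offspring", {
  set.seed(49)
  env <- scaled_env()
  cfg <- evolution_config(env, "PRO", pop_size = 20, generations = 3,
                          seed = 1)
  genomes <- replicate(20, random_genome_for(env), simplify = FALSE)
  pop <- modcost:::evaluate_population(genomes, env, cfg)
  sec1 <- pop$sec
  pop2 <- evolve_generation(pop, env, cfg)
  expect_true(all(pop2$sec >= 0 & pop2$sec <= 1))
  # survivors mix parents and offspring, so secondaries change
  expect_false(identical(sort(sec1), sort(pop2$sec)))
})

test_that("trials are deterministic given a seed and respect the alphabet", {
  env <- scaled_env()
  cfg <- evolution_config(env, "PCC_length", pop_size = 24,
                          generations = 30, seed = 123)
  t1 <- run_trial(cfg)
  t2 <- run_trial(cfg)
  expect_identical(t1$best_perf, t2$best_perf)
  expect_identical(t1$best_genome, t2$best_genome)
  expect_silent(validate_genome(t1$best_genome))
  w <- unlist(lapply(t1$best_genome$weights, as.vector))
  expect_true(all(w %in% -2:2))
  expect_length(t1$best_perf, 30L)
  # the trajectory is non-decreasing under elitist survivor selection
  expect_true(all(diff(t1$best_perf) >= 0))
})

test_that("MVG trials switch environments on schedule", {
  a <- build_retina_environment("and")
  o <- build_retina_environment("or")
  cfg <- evolution_config(mvg_schedule(a, o, period = 5), "PCC_length",
                          pop_size = 24, generations = 12, seed = 5)
  tr <- run_trial(cfg)
  expect_length(tr$best_perf, 12L)
  expect_s3_class(tr$best_genome, "network_genome")
})

test_that("randomized input coordinates permute x within the row", {
  env <- scaled_env()
  set.seed(7)
  env2 <- randomize_input_coords(env)
  expect_setequal(env2$io_coords$input[, 1], env$io_coords$input[, 1])
  expect_identical(env2$io_coords$input[, 2], env$io_coords$input[, 2])
  expect_identical(env2$io_coords$output, env$io_coords$output)
  # trials with the flag remain deterministic under the seed
  cfg <- evolution_config(env, "PCC_length", pop_size = 16,
                          generations = 15, seed = 5,
                          randomize_coords = TRUE)
  t1 <- run_trial(cfg)
  t2 <- run_trial(cfg)
  expect_identical(t1$best_perf, t2$best_perf)
  expect_identical(t1$final_cost, t2$final_cost)
})

test_that("mutational removal bias alone does not strip connections under PA", {
  env <- scaled_env()
  cfg <- biased_mutation_preset(env, pop_size = 100, generations = 600,
                                seed = 77)
  expect_identical(cfg$treatment, "PA")
  expect_equal(cfg$mutation$remove / cfg$mutation$add, 10)
  tr <- run_trial(cfg, compute_q = FALSE)
  # connection counts stay far above the cost-selected regime (~20-30)
  expect_gt(tr$final_cost[["count"]], 45)
})

test_that("real-valued weights still evolve sparse, modular cost-selected networks", {
  env <- scaled_env()
  cfg <- evolution_config(env, "PCC_length", weight_mode = "real",
                          pop_size = 150, generations = 3000, seed = 13)
  tr <- run_trial(cfg)
  expect_true(any(unlist(tr$best_genome$weights) %% 1 != 0))
  expect_silent(validate_genome(tr$best_genome))
  # direction: the evolved network is sparse relative to random genomes
  # (~80 connections) and visibly modular
  expect_lt(tr$final_cost[["count"]], 60)
  expect_gt(tr$final_q, 0.25)
})

test_that("snapshots are recorded at the requested cadence", {
  env <- scaled_env()
  cfg <- evolution_config(env, "PA", pop_size = 20, generations = 10,
                          seed = 9, record_snapshots = 5)
  tr <- run_trial(cfg)
  expect_named(tr$snapshots, c("5", "10"))
  expect_s3_class(tr$snapshots[["5"]], "network_genome")
})
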