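test_that("retina environments enumerate all 256 patterns with 8/16 object sets", {
  sets <- retina_object_sets()
  expect_equal(nrow(sets$left), 8L)
  expect_equal(nrow(sets$right), 8L)
  env_and <- build_retina_environment("and")
  env_or <- build_retina_environment("or")
  expect_equal(nrow(env_and$patterns), 256L)
  expect_false(any(duplicated(env_and$patterns)))
  # 8 objects per side: AND true on 8 x 8 = 64, OR false on 8 x 8 = 64
  expect_equal(sum(env_and$targets), 64L)
  expect_equal(sum(!env_or$targets), 64L)
})

test_that("subproblem answers recombine into the task targets", {
  for (mode in c("and", "or")) {
    env <- build_retina_environment(mode)
    sp <- env$subproblems
    combined <- if (mode == "and") sp[[1]]$answers & sp[[2]]$answers
    else sp[[1]]$answers | sp[[2]]$answers
    expect_identical(combined, env$targets[, 1])
    expect_length(intersect(sp[[1]]$inputs, sp[[2]]$inputs), 0)
  }
  env <- build_xor_environment("hierarchical_xor")
  sp <- env$subproblems
  expect_identical(cbind(sp[[1]]$answers, sp[[2]]$answers),
                   unname(env$targets))
})

test_that("non-modular retina counts ON pixels", {
  env <- build_nonmodular_retina_environment()
  expect_false(env$targets[1, 1])                 # all OFF
  expect_true(env$targets[256, 1])                # all ON
  expect_equal(sum(env$targets), sum(choose(8, 4:8)))  # 163
  expect_length(env$subproblems, 0)
  exact <- build_nonmodular_retina_environment("exactly_4")
  expect_equal(sum(exact$targets), choose(8, 4))
})

test_that("XOR environments have the stated shapes and truth tables", {
  fx <- build_xor_environment("five_xor")
  expect_equal(dim(fx$patterns), c(1024L, 10L))
  expect_equal(ncol(fx$targets), 5L)
  expect_equal(fx$io_coords$output[, "x"], c(-4, -2, 0, 2, 4))
  # pair (ON, ON) -> false; (ON, OFF) -> true
  both_on <- fx$patterns[, 1] & fx$patterns[, 2]
  expect_false(any(fx$targets[both_on, 1]))
  hx <- build_xor_environment("hierarchical_xor")
  expect_equal(dim(hx$patterns), c(256L, 8L))
  # one ON pixel in a half makes that half's output true (odd parity)
  p <- which(hx$patterns[, 1] & rowSums(hx$patterns) == 1)
  expect_true(all(hx$targets[p, 1]))
  expect_false(any(hx$targets[p, 2]))
})

test_that("performance counts classified answers and saturates at 1", {
  env <- build_xor_environment("hierarchical_xor")
  sol <- hier_xor_solution(env)
  expect_equal(performance(sol, env), 1.0)
  # a hand-built exact solver of one XOR pair, with the four remaining
  # outputs constant-true: (1 + 4 * 0.5) / 5 of answers correct
  fx <- build_xor_environment("five_xor")
  expect_equal(performance(xor_pair_genome(fx, 1), fx), 0.6)
  # always-false network: threshold 1 on the output, no connections
  env_and <- build_retina_environment("and")
  g_false <- empty_genome(env_and)
  g_false$thresholds[[5]] <- 1L
  expect_equal(performance(g_false, env_and), 192 / 256)
  # complementary constant networks sum to 1 on any environment
  g_true <- empty_genome(env_and)
  g_true$thresholds[[5]] <- -1L
  expect_equal(performance(g_false, env_and) + performance(g_true, env_and),
               1.0)
  expect_error(performance(empty_genome(env), env_and), "match")
})

test_that("MVG schedules alternate deterministically", {
  a <- build_retina_environment("and")
  o <- build_retina_environment("or")
  sch <- mvg_schedule(a, o, period = 20)
  for (g in 0:19) expect_identical(environment_at(sch, g)$name, a$name)
  expect_identical(environment_at(sch, 20)$name, o$name)
  expect_identical(environment_at(sch, 40)$name, a$name)
  fast <- mvg_schedule(a, o, period = 1)
  expect_identical(environment_at(fast, 0)$name, a$name)
  expect_identical(environment_at(fast, 1)$name, o$name)
  expect_identical(environment_at(fast, 2)$name, a$name)
  expect_error(mvg_schedule(a, build_xor_environment("five_xor")))
})

test_that("truth tables export round-trip through CSV", {
  env <- build_retina_environment("and")
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(env, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 256L)
  expect_equal(sum(df$target1), 64L)
})
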