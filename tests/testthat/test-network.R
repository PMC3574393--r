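test_that("node transfer function: fixed points, saturation, threshold", {
  expect_identical(node_output(numeric(0), numeric(0), 0), 0)
  # strong excitation saturates to +1
  expect_equal(node_output(2, 1, 0), 1, tolerance = 1e-12)
  # weighted sum exactly at the threshold sits on the transition point
  expect_identical(node_output(c(1, 1), c(1, 1), 2), 0)
  # strictly increasing in the weighted input sum
  v <- vapply(seq(-2, 2, by = 0.25), function(s)
    node_output(1, s, 0, lambda = 1), numeric(1))
  expect_true(all(diff(v) > 0))
  # +b convention flips the role of the threshold
  expect_equal(node_output(1, 1, 1, bias_sign = 1),
               node_output(1, 1, -1, bias_sign = -1))
})

test_that("classification boundary is exactly >= 0", {
  expect_true(classify(0))
  expect_false(classify(-0.001))
  expect_true(classify(1))
  expect_identical(classify(c(-1, 0, 1)), c(FALSE, TRUE, TRUE))
})

test_that("genome invariants are enforced", {
  expect_error(network_genome(c(5)), "layers")
  g <- network_genome(c(2, 1))
  g$weights[[1]][1, 1] <- 3L
  expect_error(validate_genome(g), "weights")
  g <- network_genome(c(2, 1))
  g$thresholds[[2]][1] <- -3L
  expect_error(validate_genome(g), "thresholds")
  # real mode accepts fractional values within range
  gr <- network_genome(c(2, 1), list(matrix(c(0.5, -1.7), 2, 1)),
                       mode = "real")
  expect_equal(n_connections(gr), 2L)
})

test_that("layer-wise evaluation handles empty genomes and mismatches", {
  g <- network_genome(c(3, 2, 1))
  g$thresholds[[2]] <- c(1L, -2L)
  g$thresholds[[3]] <- 2L
  acts <- evaluate_network(g, c(1, -1, 1))
  # no incoming connections: every node outputs tanh(-lambda * b)
  expect_equal(acts[[2]][1, ], tanh(-20 * c(1, -2)))
  expect_equal(acts[[3]][1, 1], tanh(-20 * 2))
  expect_error(evaluate_network(g, c(1, -1)), "does not match")
})

test_that("a direct wire propagates the input sign", {
  g <- network_genome(c(2, 2, 1))
  g$weights[[1]][1, 1] <- 2L
  g$weights[[2]][1, 1] <- 2L
  for (x in c(-1, 1)) {
    out <- network_outputs(g, c(x, 1))
    expect_equal(sign(out[1, 1]), x)
  }
})

test_that("evaluation is deterministic and bounded on random genomes", {
  set.seed(11)
  env <- scaled_env()
  for (i in 1:20) {
    g <- random_genome_for(env)
    a1 <- evaluate_network(g, env$X)
    a2 <- evaluate_network(g, env$X)
    expect_identical(a1, a2)
    expect_true(all(vapply(a1, function(m) all(abs(m) <= 1), logical(1))))
  }
})

test_that("lambda = 20 behaves as a hard threshold away from the boundary", {
  set.seed(12)
  for (i in 1:200) {
    w <- sample(c(-2L, -1L, 1L, 2L), 4, replace = TRUE)
    y <- runif(4, -1, 1)
    b <- sample(-2:2, 1)
    s <- sum(w * y) - b
    if (abs(s) > 0.05)
      expect_identical(classify(node_output(w, y, b)), s > 0)
  }
})

test_that("node table and displayed graph drop connectionless nodes", {
  env <- scaled_env()
  g <- empty_genome(env)
  g$weights[[1]][1, 1] <- 1L
  g$weights[[2]][1, 1] <- 1L
  nt <- node_table(g)
  expect_equal(sum(nt$displayed), 3L)
  dg <- displayed_graph(g)
  expect_equal(rownames(dg$A), c("I1", "H1.1", "H2.1"))
  expect_equal(sum(dg$A), 2L)
  ig <- as_igraph_genome(g)
  expect_s3_class(ig, "igraph")
  expect_equal(igraph::vcount(ig), 3L)
})
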