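test_that("free nodes sit at the mean of their neighbours", {
  # one hidden node between two fixed nodes at (0,0) and (2,0)
  g <- network_genome(c(1, 1, 1),
                      io_coords = list(input = cbind(0, 0),
                                       output = cbind(2, 0)))
  g$weights[[1]][1, 1] <- 1L
  g$weights[[2]][1, 1] <- 1L
  pl <- optimal_placement(g)
  expect_equal(pl$coords[2, ], c(1, 0))
  expect_equal(pl$cost, 2)  # two unit-length connections
  # a pendant hidden node collapses onto its only neighbour
  g2 <- network_genome(c(1, 1, 1),
                       io_coords = list(input = cbind(-3.5, 0),
                                        output = cbind(4, 0)))
  g2$weights[[1]][1, 1] <- 1L
  pl2 <- optimal_placement(g2)
  expect_equal(pl2$coords[2, ], c(-3.5, 0))
  expect_equal(pl2$cost, 0)
})

test_that("direct input-output wiring uses fixed coordinates only", {
  env <- scaled_env()
  # route through the hidden stack: I8 (3.5, 0) -> ... -> O1 (4, 0)
  g <- network_genome(c(1, 1),
                      io_coords = list(input = cbind(3.5, 0),
                                       output = cbind(4, 0)))
  g$weights[[1]][1, 1] <- 1L
  expect_equal(connection_cost(g, "length_sq"), 0.25)
  expect_equal(connection_cost(g, "count"), 1)
  expect_equal(connection_cost(empty_genome(env), "length_sq"), 0)
  expect_equal(connection_cost(empty_genome(env), "count"), 0)
})

test_that("analytic placement matches a numeric optimizer on random genomes", {
  set.seed(21)
  env <- scaled_env()
  for (i in 1:12) {
    g <- random_genome_for(env)
    # sparsify so free components of several shapes occur
    for (l in seq_along(g$weights)) {
      drop <- runif(length(g$weights[[l]])) < 0.7
      g$weights[[l]][drop] <- 0L
    }
    expect_equal(optimal_placement(g)$cost, numeric_placement_cost(g),
                 tolerance = 1e-6)
  }
})

test_that("placement is a local minimum and reproducible", {
  set.seed(22)
  env <- scaled_env()
  g <- random_genome_for(env)
  pl1 <- optimal_placement(g)
  pl2 <- optimal_placement(g)
  expect_identical(pl1, pl2)
  nt <- node_table(g)
  hidden <- which(nt$role == "hidden" & nt$degree > 0)
  ed <- NULL
  for (h in hidden[1:4]) {
    for (axis in 1:2) for (eps in c(-1e-4, 1e-4)) {
      xy <- pl1$coords
      xy[h, axis] <- xy[h, axis] + eps
      # recompute cost at perturbed coordinates
      ls <- g$layers
      off <- c(0L, cumsum(ls))
      cost <- 0
      for (l in seq_along(g$weights)) {
        idx <- which(g$weights[[l]] != 0L, arr.ind = TRUE)
        if (!nrow(idx)) next
        a <- off[l] + idx[, 1]
        b <- off[l + 1] + idx[, 2]
        d <- xy[a, , drop = FALSE] - xy[b, , drop = FALSE]
        cost <- cost + sum(d * d)
      }
      expect_gte(cost, pl1$cost - 1e-12)
    }
  }
})

test_that("removing a connection never increases either cost", {
  set.seed(23)
  env <- scaled_env()
  for (i in 1:5) {
    g <- random_genome_for(env)
    idx <- which(g$weights[[1]] != 0L)
    g2 <- g
    g2$weights[[1]][sample(idx, 1)] <- 0L
    expect_lte(connection_cost(g2, "length_sq"),
               connection_cost(g, "length_sq") + 1e-12)
    expect_lt(connection_cost(g2, "count"), connection_cost(g, "count"))
  }
})

test_that("count cost ignores coordinates and weight magnitudes", {
  g <- network_genome(c(2, 1),
                      io_coords = list(input = cbind(c(0, 1), 0),
                                       output = cbind(99, 0)))
  g$weights[[1]][, 1] <- c(2L, -1L)
  expect_equal(connection_cost(g, "count"), 2)
  g$io_coords$output[1, 1] <- 0
  expect_equal(connection_cost(g, "count"), 2)
})
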