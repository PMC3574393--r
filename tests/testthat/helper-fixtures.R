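# shared fixtures, all built in code

# adjacency of two disjoint directed 2-cycles: a<->b, c<->d
two_cycles_adj <- function() {
  A <- matrix(0L, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  A["a", "b"] <- A["b", "a"] <- A["c", "d"] <- A["d", "c"] <- 1L
  A
}

# two directed triangles (3-cycles), disjoint
two_triangles_adj <- function() {
  A <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4)))
    A[e[1], e[2]] <- 1L
  A
}

# two dense directed clusters joined by a single edge
two_clusters_adj <- function() {
  A <- matrix(0L, 8, 8)
  for (i in 1:4) for (j in 1:4) if (i != j) A[i, j] <- 1L
  for (i in 5:8) for (j in 5:8) if (i != j) A[i, j] <- 1L
  A[4, 5] <- 1L
  A
}

# random directed graph on n nodes, ensuring at least one edge
random_digraph <- function(n, p = 0.3) {
  repeat {
    A <- matrix(rbinom(n * n, 1, p), n, n)
    diag(A) <- 0L
    if (sum(A) > 0) return(A)
  }
}

# genome whose hidden node H1.1 computes the left-object predicate of the
# default retina sets exactly: w = (2,1,1,1) from the left inputs, b = 1
left_detector_genome <- function(env) {
  g <- empty_genome(env)
  g$weights[[1]][1:4, 1] <- c(2L, 1L, 1L, 1L)
  g$thresholds[[2]][1] <- 1L
  # give it an outgoing edge so it is displayed
  g$weights[[2]][1, 1] <- 1L
  validate_genome(g)
  g
}

# exact XOR sub-network for one input pair of the five-XOR task:
# h1 detects (on, off), h2 detects (off, on), output fires iff either does
xor_pair_genome <- function(env, pair = 1L) {
  g <- empty_genome(env)
  i1 <- 2L * pair - 1L
  i2 <- 2L * pair
  h1 <- 2L * pair - 1L
  h2 <- 2L * pair
  g$weights[[1]][i1, h1] <- 1L
  g$weights[[1]][i2, h1] <- -1L
  g$weights[[1]][i1, h2] <- -1L
  g$weights[[1]][i2, h2] <- 1L
  g$thresholds[[2]][c(h1, h2)] <- 1L
  g$weights[[2]][h1, pair] <- 2L
  g$weights[[2]][h2, pair] <- 2L
  g$thresholds[[3]][pair] <- -1L
  validate_genome(g)
  g
}

# exact solution of the hierarchical-XOR task (layers 8-8-4-4-2):
# layer 2 holds (on,off)/(off,on) detectors per input pair, layer 3 one
# +-1 XOR value per pair, layer 4 detectors over XOR-value pairs, outputs
# combine them
hier_xor_solution <- function(env) {
  g <- empty_genome(env)
  for (k in 1:4) {  # first-level XORs over input pairs (2k-1, 2k)
    i1 <- 2L * k - 1L
    i2 <- 2L * k
    g$weights[[1]][i1, i1] <- 1L   # detector d_{2k-1}: i1 on, i2 off
    g$weights[[1]][i2, i1] <- -1L
    g$weights[[1]][i1, i2] <- -1L  # detector d_{2k}: i1 off, i2 on
    g$weights[[1]][i2, i2] <- 1L
    g$thresholds[[2]][c(i1, i2)] <- 1L
    g$weights[[2]][i1, k] <- 1L    # x_k = d_{2k-1} OR d_{2k}
    g$weights[[2]][i2, k] <- 1L
    g$thresholds[[3]][k] <- -1L
  }
  for (h in 1:2) {  # second-level XOR over (x_{2h-1}, x_{2h})
    x1 <- 2L * h - 1L
    x2 <- 2L * h
    g$weights[[3]][x1, x1] <- 1L
    g$weights[[3]][x2, x1] <- -1L
    g$weights[[3]][x1, x2] <- -1L
    g$weights[[3]][x2, x2] <- 1L
    g$thresholds[[4]][c(x1, x2)] <- 1L
    g$weights[[4]][x1, h] <- 2L
    g$weights[[4]][x2, h] <- 2L
    g$thresholds[[5]][h] <- -1L
  }
  validate_genome(g)
  g
}

# tiny two-objective population with known Pareto structure
chain_objectives <- function(n) {
  # strictly ordered on both objectives: a chain under full dominance
  list(perf = seq_len(n) / n, sec = seq_len(n))
}

scaled_env <- function() build_retina_environment("and")

tiny_config <- function(env, treatment = "PCC_length", ...) {
  evolution_config(env, treatment, pop_size = 20L, generations = 10L,
                   seed = 1L, ...)
}

# numeric oracle: minimize total squared length over free coordinates with
# a generic optimizer
numeric_placement_cost <- function(genome) {
  ls <- genome$layers
  L <- length(ls)
  n <- sum(ls)
  off <- c(0L, cumsum(ls))
  A <- matrix(0, n, n)
  for (l in seq_len(L - 1L)) {
    w <- genome$weights[[l]] != 0L
    A[off[l] + seq_len(ls[l]), off[l + 1L] + seq_len(ls[l + 1L])] <- w + 0
  }
  A <- A + t(A)
  ed <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  fixed <- c(rep(TRUE, ls[1]), rep(FALSE, n - ls[1] - ls[L]),
             rep(TRUE, ls[L]))
  xy0 <- matrix(0, n, 2)
  xy0[seq_len(ls[1]), ] <- genome$io_coords$input[, 1:2]
  xy0[off[L] + seq_len(ls[L]), ] <- genome$io_coords$output[, 1:2]
  free <- which(!fixed)
  if (!length(free) || !nrow(ed)) {
    d <- xy0[ed[, 1], , drop = FALSE] - xy0[ed[, 2], , drop = FALSE]
    return(sum(d * d))
  }
  obj <- function(par) {
    xy <- xy0
    xy[free, ] <- matrix(par, ncol = 2)
    d <- xy[ed[, 1], , drop = FALSE] - xy[ed[, 2], , drop = FALSE]
    sum(d * d)
  }
  res <- optim(rep(0, 2 * length(free)), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  res$value
}

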