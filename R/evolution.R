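#' Configuration for an evolutionary run
#'
#' Bundles the treatment, task, and algorithm parameters of one trial.
#' Defaults reproduce the full-scale study conditions (population 1000,
#' 25000 generations, secondary objective applied with probability 0.25);
#' [scaled_preset()] provides reduced sizes for quick direction checks.
#'
#' Treatments:
#' \describe{
#'   \item{`PA`}{performance alone (single objective).}
#'   \item{`PCC_length`}{performance + minimize summed squared wiring
#'     length under optimal node placement.}
#'   \item{`PCC_count`}{performance + minimize number of connections.}
#'   \item{`PRO`}{performance + a random secondary objective (control):
#'     each new individual is assigned a fresh uniform random number which
#'     is maximized.}
#' }
#'
#' @param env A `task_env`, or an `mvg_schedule` for modularly varying
#'   goals.
#' @param treatment One of `"PA"`, `"PCC_length"`, `"PCC_count"`, `"PRO"`.
#' @param p_cost Probability the secondary objective is consulted in a
#'   dominance comparison (default 0.25).
#' @param pop_size Population size (default 1000).
#' @param generations Number of generations (default 25000).
#' @param mutation List of rates: `add` and `remove` are per-network
#'   probabilities of a single connection addition/removal (default 0.20
#'   each); `threshold` is the per-node probability of a +-1 threshold
#'   change (default 1/24); `weight` is the numerator of the
#'   per-connection change probability `weight / n_connections`
#'   (default 2.0).
#' @param weight_mode `"integer"` (default) or `"real"` (Gaussian weight
#'   perturbation, sd `sigma`, clamped to \[-2, 2\]).
#' @param sigma Gaussian mutation sd for `weight_mode = "real"`.
#' @param lambda,bias_sign Transfer-function parameters.
#' @param seed Master seed of the trial.
#' @param randomize_coords Permute the input nodes' x-coordinates at the
#'   start of each trial (the randomized-coordinates control; only
#'   meaningful with a wiring-length cost).
#' @param record_snapshots Store the best genome every this many
#'   generations (0 = never).
#' @return An object of class `evo_config`.
#' @export
evolution_config <- function(env,
                             treatment = c("PCC_length", "PA", "PCC_count",
                                           "PRO"),
                             p_cost = 0.25,
                             pop_size = 1000L,
                             generations = 25000L,
                             mutation = list(add = 0.20, remove = 0.20,
                                             threshold = 1 / 24,
                                             weight = 2.0),
                             weight_mode = c("integer", "real"),
                             sigma = 0.5,
                             lambda = 20, bias_sign = -1,
                             seed = 1L,
                             randomize_coords = FALSE,
                             record_snapshots = 0L) {
  treatment <- match.arg(treatment)
  weight_mode <- match.arg(weight_mode)
  defaults <- list(add = 0.20, remove = 0.20, threshold = 1 / 24,
                   weight = 2.0)
  mutation <- utils::modifyList(defaults, as.list(mutation))
  if (!(inherits(env, "task_env") || inherits(env, "mvg_schedule")))
    stop("env must be a task_env or mvg_schedule")
  if (p_cost < 0 || p_cost > 1) stop("p_cost must be in [0, 1]")
  for (r in c("add", "remove", "threshold"))
    if (mutation[[r]] < 0 || mutation[[r]] > 1)
      stop("mutation rate '", r, "' must be in [0, 1]")
  if (mutation$weight < 0) stop("mutation rate 'weight' must be >= 0")
  stopifnot(pop_size >= 2, generations >= 1, sigma > 0, lambda > 0)
  structure(list(env = env, treatment = treatment, p_cost = p_cost,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation = mutation, weight_mode = weight_mode,
                 sigma = sigma, lambda = lambda, bias_sign = bias_sign,
                 seed = as.integer(seed),
                 randomize_coords = isTRUE(randomize_coords),
                 record_snapshots = as.integer(record_snapshots)),
            class = "evo_config")
}

#' Scaled-down preset of an evolution configuration
#'
#' The full study conditions (50 trials of population 1000 over 25000
#' generations) take tens of CPU hours; this preset keeps every mechanism
#' identical but shrinks population and generations for direction checks.
#'
#' @param env Task environment or MVG schedule.
#' @param pop_size,generations Reduced sizes.
#' @param ... Passed to [evolution_config()].
#' @return An `evo_config`.
#' @export
scaled_preset <- function(env, pop_size = 200L, generations = 2000L, ...) {
  evolution_config(env, pop_size = pop_size, generations = generations, ...)
}

#' Biased-mutation robustness preset
#'
#' Performance-alone selection with connection-removal events an order of
#' magnitude more probable than additions.  The control asks whether
#' sparse, modular networks can be produced by mutational bias rather
#' than a cost objective: under performance-alone selection they are not
#' (connection counts stay far above cost-selected levels).
#'
#' @param env Task environment.
#' @param bias Removal-to-addition ratio (default 10).
#' @param add Addition probability (default 0.05, so removal is 0.5).
#' @param ... Passed to [evolution_config()].
#' @return An `evo_config` with treatment `"PA"`.
#' @export
biased_mutation_preset <- function(env, bias = 10, add = 0.05, ...) {
  evolution_config(env, treatment = "PA",
                   mutation = list(add = add, remove = min(1, add * bias)),
                   ...)
}

#' @export
print.evo_config <- function(x, ...) {
  envname <- if (inherits(x$env, "mvg_schedule"))
    paste0("MVG(", x$env$envs[[1]]$name, " <-> ", x$env$envs[[2]]$name,
           ", E=", x$env$period, ")")
  else x$env$name
  cat("Evolution config:", x$treatment, "on", envname, "\n")
  cat("  pop", x$pop_size, " generations", x$generations,
      " p_cost", x$p_cost, " weights", x$weight_mode, " seed", x$seed, "\n")
  invisible(x)
}

env_at_generation <- function(config, generation) {
  if (inherits(config$env, "mvg_schedule"))
    environment_at(config$env, generation)
  else config$env
}

# ---- mutation ---------------------------------------------------------------

#' Mutate a network genome
#'
#' Applies, independently and in fixed order (the events are not mutually
#' exclusive):
#' \enumerate{
#'   \item with probability `add` (0.20): add a single connection, chosen
#'     uniformly among absent consecutive-layer pairs;
#'   \item with probability `remove` (0.20): remove a single uniformly
#'     chosen existing connection (no-op on a connectionless genome);
#'   \item each node, with probability `threshold` (1/24): increment or
#'     decrement its threshold (equally probable); results outside
#'     \{-2, ..., 2\} are ignored;
#'   \item each connection, with probability `weight / n` (n = current
#'     connection count): increment or decrement its weight; in integer
#'     mode the step skips 0 (-1 + 1 -> +1, +1 - 1 -> -1) and results
#'     outside \{-2, ..., 2\} are ignored; in real mode the weight is
#'     perturbed by a N(0, sigma^2) draw and clamped to \[-2, 2\].
#' }
#' A newly added connection receives a uniform weight from \{-2, -1, 1, 2\}
#' (integer mode) or Uniform(-2, 2) (real mode).
#'
#' The returned genome carries an attribute `"events"` counting attempted
#' add/remove draws and per-node/per-connection mutation attempts
#' (attempts are counted even when the resulting value is out of range and
#' ignored).
#'
#' @param genome A `network_genome`.
#' @param config An `evo_config` (only the `mutation`, `weight_mode` and
#'   `sigma` fields are used).
#' @return The mutated `network_genome`.
#' @export
mutate <- function(genome, config) {
  rates <- config$mutation
  real <- !is.null(genome$mode) && genome$mode == "real"
  W <- genome$weights
  nl <- length(W)
  events <- c(add = 0L, remove = 0L, threshold = 0L, weight = 0L)

  # (i) add a connection
  if (stats::runif(1) < rates$add) {
    events[1L] <- 1L
    absent <- lapply(W, function(w) which(w == 0))
    tot <- sum(lengths(absent))
    if (tot > 0L) {
      k <- sample.int(tot, 1L)
      for (l in seq_len(nl)) {
        nL <- length(absent[[l]])
        if (k <= nL) {
          W[[l]][absent[[l]][k]] <-
            if (real) {
              v <- stats::runif(1, -2, 2)
              if (v == 0) 1e-6 else v
            } else sample(c(-2L, -1L, 1L, 2L), 1L)
          break
        }
        k <- k - nL
      }
    }
  }

  # (ii) remove a connection
  if (stats::runif(1) < rates$remove) {
    events[2L] <- 1L
    present <- lapply(W, function(w) which(w != 0))
    tot <- sum(lengths(present))
    if (tot > 0L) {
      k <- sample.int(tot, 1L)
      for (l in seq_len(nl)) {
        nL <- length(present[[l]])
        if (k <= nL) {
          W[[l]][present[[l]][k]] <- if (real) 0 else 0L
          break
        }
        k <- k - nL
      }
    }
  }

  # (iii) thresholds: per node
  for (l in seq_along(genome$thresholds)) {
    b <- genome$thresholds[[l]]
    hit <- which(stats::runif(length(b)) < rates$threshold)
    events[3L] <- events[3L] + length(hit)
    if (length(hit)) {
      if (real) {
        nb <- b[hit] + stats::rnorm(length(hit), 0, config$sigma)
        b[hit] <- pmin(2, pmax(-2, nb))
      } else {
        step <- sample(c(-1L, 1L), length(hit), replace = TRUE)
        nb <- b[hit] + step
        ok <- abs(nb) <= 2L
        b[hit[ok]] <- nb[ok]
      }
      genome$thresholds[[l]] <- b
    }
  }

  # (iv) weights: per connection, probability weight / n
  ncon <- sum(vapply(W, function(w) sum(w != 0), numeric(1)))
  if (ncon > 0L) {
    pw <- min(1, rates$weight / ncon)
    for (l in seq_len(nl)) {
      idx <- which(W[[l]] != 0)
      if (!length(idx)) next
      hit <- idx[stats::runif(length(idx)) < pw]
      events[4L] <- events[4L] + length(hit)
      if (length(hit)) {
        w <- W[[l]][hit]
        if (real) {
          nw <- pmin(2, pmax(-2, w + stats::rnorm(length(hit), 0,
                                                  config$sigma)))
          nw[nw == 0] <- 1e-6
          W[[l]][hit] <- nw
        } else {
          step <- sample(c(-1L, 1L), length(hit), replace = TRUE)
          nw <- w + step
          nw <- ifelse(nw == 0L, w + 2L * step, nw)  # 0 is not a weight
          ok <- abs(nw) <= 2L
          W[[l]][hit[ok]] <- nw[ok]
        }
      }
    }
  }

  genome$weights <- W
  attr(genome, "events") <- events
  genome
}

# ---- stochastic Pareto dominance -------------------------------------------

#' Stochastic Pareto dominance
#'
#' Dominance in which the secondary objective is consulted only with
#' probability `p`: a fresh r ~ Uniform(0, 1) is drawn; if r > p, `a`
#' dominates `b` iff it is strictly better on the first objective; if
#' r <= p, standard Pareto dominance applies (not worse on either
#' objective, strictly better on at least one).  Objectives are oriented
#' so that larger is better (costs enter negated).  With a single
#' objective the comparison is deterministic.
#'
#' @param a,b Numeric objective vectors (length 1 or 2), larger = better.
#' @param p Probability of consulting the secondary objective.
#' @return Logical: does `a` stochastically dominate `b`?
#' @export
stochastic_dominates <- function(a, b, p = 0.25) {
  if (length(a) != length(b)) stop("objective vectors differ in length")
  if (length(a) == 1L) return(a[1L] > b[1L])
  r <- stats::runif(1)
  if (r > p) a[1L] > b[1L]
  else all(a >= b) && any(a > b)
}

# vectorized dominance over index pairs (fresh r per comparison)
stoch_dom_vec <- function(p1, s1, p2, s2, p) {
  if (is.null(s1)) return(p1 > p2)
  r <- stats::runif(length(p1))
  ifelse(r > p, p1 > p2, (p1 >= p2 & s1 >= s2) & (p1 > p2 | s1 > s2))
}

# full pairwise dominance matrix D[i, j] = (i dominates j), one fresh r
# per ordered pair
dominance_matrix <- function(perf, sec, p) {
  n <- length(perf)
  Dperf <- outer(perf, perf, ">")
  if (is.null(sec)) return(Dperf)
  ge1 <- outer(perf, perf, ">=")
  ge2 <- outer(sec, sec, ">=")
  gt2 <- outer(sec, sec, ">")
  Dpar <- ge1 & ge2 & (Dperf | gt2)
  R <- matrix(stats::runif(n * n), n, n)
  out <- Dpar
  use1 <- R > p
  out[use1] <- Dperf[use1]
  out
}

#' Stochastic non-dominated sorting
#'
#' Peels a population into Pareto layers under stochastic dominance: layer
#' 1 is the set of individuals not stochastically dominated by any other;
#' those are removed and the operation repeats.  Every pairwise test uses
#' its own fresh random draw.
#'
#' @param perf Numeric vector of first-objective scores (performance).
#' @param sec Numeric vector of secondary scores oriented so larger is
#'   better (e.g. negated cost), or `NULL` for a single objective.
#' @param p Probability of consulting the secondary objective.
#' @return Integer vector of ranks (1 = first layer).
#' @export
stochastic_nondominated_sort <- function(perf, sec = NULL, p = 0.25) {
  n <- length(perf)
  D <- dominance_matrix(perf, sec, p)
  rank <- integer(n)
  remaining <- rep(TRUE, n)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    idx <- which(remaining)
    dominated <- colSums(D[idx, idx, drop = FALSE]) > 0L
    layer <- idx[!dominated]
    if (!length(layer)) layer <- idx  # unreachable: dominance is acyclic
    rank[layer] <- k
    remaining[layer] <- FALSE
  }
  rank
}

#' NSGA-II crowding distance within one Pareto layer
#'
#' Sum over objectives of the normalized gap between each individual's
#' neighbours when sorted by that objective; boundary individuals receive
#' infinite distance.
#'
#' @param obj Numeric matrix, one row per individual, one column per
#'   objective.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  d <- numeric(n)
  for (j in seq_len(ncol(obj))) {
    o <- order(obj[, j])
    rng <- obj[o[n], j] - obj[o[1L], j]
    d[o[c(1L, n)]] <- Inf
    if (n > 2L && rng > 0)
      d[o[2:(n - 1L)]] <- d[o[2:(n - 1L)]] +
        (obj[o[3:n], j] - obj[o[1:(n - 2L)], j]) / rng
  }
  d
}

# ranks + crowding for a population
rank_and_crowd <- function(perf, sec, p) {
  rank <- stochastic_nondominated_sort(perf, sec, p)
  crowd <- numeric(length(perf))
  obj <- if (is.null(sec)) cbind(perf) else cbind(perf, sec)
  for (k in unique(rank)) {
    m <- which(rank == k)
    crowd[m] <- crowding_distance(obj[m, , drop = FALSE])
  }
  list(rank = rank, crowd = crowd)
}

#' Binary tournament parent selection
#'
#' Two individuals are drawn uniformly; if one stochastically dominates
#' the other it is selected; otherwise the lower Pareto rank wins, then
#' the larger crowding distance, then a coin flip.
#'
#' @param perf,sec Objective vectors (see
#'   [stochastic_nondominated_sort()]).
#' @param rank,crowd Precomputed ranks and crowding distances.
#' @param p Probability of consulting the secondary objective.
#' @param k Number of parents to select.
#' @return Integer vector of `k` selected indices.
#' @export
select_parents <- function(perf, sec, rank, crowd, p, k) {
  n <- length(perf)
  i <- sample.int(n, k, replace = TRUE)
  j <- sample.int(n, k, replace = TRUE)
  s_i <- if (is.null(sec)) NULL else sec[i]
  s_j <- if (is.null(sec)) NULL else sec[j]
  dij <- stoch_dom_vec(perf[i], s_i, perf[j], s_j, p)
  dji <- stoch_dom_vec(perf[j], s_j, perf[i], s_i, p)
  pick_i <- dij |
    (!dij & !dji & (rank[i] < rank[j] |
                      (rank[i] == rank[j] & crowd[i] > crowd[j]) |
                      (rank[i] == rank[j] & crowd[i] == crowd[j] &
                         stats::runif(k) < 0.5)))
  ifelse(pick_i, i, j)
}

# ---- generation loop --------------------------------------------------------

secondary_score <- function(genomes, treatment) {
  na <- rep(NA_real_, length(genomes))
  switch(treatment,
         PA = list(sec = NULL, cost = na),
         PCC_length = {
           cost <- vapply(genomes, connection_cost, numeric(1),
                          kind = "length_sq")
           list(sec = -cost, cost = cost)
         },
         PCC_count = {
           cost <- vapply(genomes, connection_cost, numeric(1),
                          kind = "count")
           list(sec = -cost, cost = cost)
         },
         PRO = list(sec = stats::runif(length(genomes)), cost = na))
}

evaluate_population <- function(genomes, env, config) {
  perf <- vapply(genomes, performance, numeric(1), env = env,
                 lambda = config$lambda, bias_sign = config$bias_sign)
  ss <- secondary_score(genomes, config$treatment)
  list(genomes = genomes, perf = perf, sec = ss$sec, cost = ss$cost)
}

#' Advance a population by one generation
#'
#' Elitist (mu + lambda) NSGA-II step: rank the current population with
#' stochastic non-dominated sorting, select mu parents by binary
#' tournament, mutate each to produce one offspring, evaluate offspring,
#' and keep the best mu of parents plus offspring by (rank, crowding)
#' under a fresh stochastic sort.
#'
#' @param pop Population list (`genomes`, `perf`, `sec`, `cost`) as
#'   produced by internal evaluation; see [run_trial()].
#' @param env The active `task_env`.
#' @param config An `evo_config`.
#' @return The next population, same structure and size.
#' @export
evolve_generation <- function(pop, env, config) {
  n <- length(pop$genomes)
  rc <- rank_and_crowd(pop$perf, pop$sec, config$p_cost)
  idx <- select_parents(pop$perf, pop$sec, rc$rank, rc$crowd,
                        config$p_cost, n)
  off_genomes <- lapply(idx, function(i) mutate(pop$genomes[[i]], config))
  off <- evaluate_population(off_genomes, env, config)

  perf <- c(pop$perf, off$perf)
  sec <- if (is.null(pop$sec)) NULL else c(pop$sec, off$sec)
  cost <- c(pop$cost, off$cost)
  genomes <- c(pop$genomes, off$genomes)

  rc2 <- rank_and_crowd(perf, sec, config$p_cost)
  ord <- order(rc2$rank, -rc2$crowd)
  keep <- ord[seq_len(n)]
  list(genomes = genomes[keep], perf = perf[keep],
       sec = if (is.null(sec)) NULL else sec[keep],
       cost = cost[keep])
}

#' Run one evolutionary trial
#'
#' Seeds the RNG from the configuration, initializes a random population,
#' and iterates the elitist NSGA-II generation step (in compiled code;
#' [evolve_generation()] is the equivalent R reference), switching
#' environments according to the MVG schedule if one is configured and
#' recording the best performance of every generation.  The final best
#' network is the highest-performing individual of the last generation,
#' ties broken randomly.
#'
#' @param config An `evo_config`.
#' @param compute_q Compute the modularity Q of the final best network
#'   (default `TRUE`).
#' @return An object of class `evo_trial` with elements `best_perf`
#'   (per-generation vector), `best_genome`, `final_performance`,
#'   `final_cost` (both cost kinds), `final_q`, `snapshots`, `config`.
#' @export
run_trial <- function(config, compute_q = TRUE) {
  set.seed(config$seed)
  if (isTRUE(config$randomize_coords)) {
    n_in <- nrow(env_at_generation(config, 0L)$io_coords$input)
    perm <- sample.int(n_in)
    permute <- function(e) {
      e$io_coords$input[, 1L] <- e$io_coords$input[perm, 1L]
      e
    }
    if (inherits(config$env, "mvg_schedule")) {
      config$env$envs <- lapply(config$env$envs, permute)
    } else {
      config$env <- permute(config$env)
    }
  }
  env0 <- env_at_generation(config, 0L)
  res <- .engine_run(engine_problem(config), engine_params(config), list())

  best_i <- sample_argmax(res$perf)
  best <- genome_from_engine(res$genomes[[best_i]], env0$io_coords,
                             config$weight_mode)
  q <- NA_real_
  if (compute_q && n_connections(best) > 0L)
    q <- genome_modularity(best)$q
  snapshots <- lapply(res$snapshots, genome_from_engine,
                      io_coords = env0$io_coords,
                      mode = config$weight_mode)
  structure(list(
    best_perf = res$best_perf,
    best_genome = best,
    final_performance = res$perf[best_i],
    final_cost = c(length_sq = connection_cost(best, "length_sq"),
                   count = connection_cost(best, "count")),
    final_q = q,
    snapshots = snapshots,
    config = config
  ), class = "evo_trial")
}

# uniform choice among the maxima (ties broken randomly)
sample_argmax <- function(x) {
  mx <- which(x == max(x))
  if (length(mx) == 1L) mx else mx[sample.int(length(mx), 1L)]
}

# convert an integer genome to real mode (same values)
integer_to_real_genome <- function(genome) {
  network_genome(genome$layers, genome$weights, genome$thresholds,
                 genome$io_coords, mode = "real")
}

#' @export
print.evo_trial <- function(x, ...) {
  cat("Evolutionary trial (", x$config$treatment, ", seed ",
      x$config$seed, ")\n", sep = "")
  cat("  generations:", length(x$best_perf), "\n")
  cat("  final performance:", format(x$final_performance, digits = 4), "\n")
  cat("  final cost: length_sq =", format(x$final_cost[["length_sq"]],
                                          digits = 4),
      ", count =", x$final_cost[["count"]], "\n")
  cat("  final modularity Q:", format(x$final_q, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.evo_trial <- function(object, ...) {
  cat("Best-performance trajectory (quartiles over generations):\n")
  print(stats::quantile(object$best_perf))
  print(object)
}

#' Plot the best-performance trajectory of a trial
#'
#' @param x An `evo_trial`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.evo_trial <- function(x, ...) {
  graphics::plot(seq_along(x$best_perf), x$best_perf, type = "l",
                 xlab = "generation", ylab = "best performance",
                 ylim = c(0, 1), ...)
  invisible(x)
}
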