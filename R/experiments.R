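#' Percentile bootstrap confidence interval of the median
#'
#' Resamples the data with replacement (default 5000 times) and returns
#' the sample median together with the percentile interval of the
#' bootstrapped medians.
#'
#' @param values Non-empty numeric vector.
#' @param n_resamples Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(median, lo, hi)`.
#' @export
bootstrap_median_ci <- function(values, n_resamples = 5000L, level = 0.95) {
  if (!length(values)) stop("empty input")
  n <- length(values)
  meds <- vapply(seq_len(n_resamples), function(i)
    stats::median(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE)
  c(median = stats::median(values), lo = ci[1L], hi = ci[2L])
}

#' Centered running-median filter
#'
#' Smooths a series with a centered running median of the given window;
#' near the edges the window is truncated to the available points.
#'
#' @param series Numeric vector.
#' @param window Window size, >= 1 (default 200).
#' @return Smoothed numeric vector, same length.
#' @export
median_filter_smooth <- function(series, window = 200L) {
  stopifnot(window >= 1)
  n <- length(series)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  vapply(seq_len(n), function(i)
    stats::median(series[max(1L, i - half_lo):min(n, i + half_hi)]),
    numeric(1))
}

#' Search-space accounting for an environment's architecture
#'
#' Counts the evolvable parameters of the genome encoding: one weight
#' slot per consecutive-layer node pair plus one threshold per node
#' (thresholds are stored for every node).  Each parameter takes one of
#' five values (weights: four non-zero values or absent; thresholds:
#' \{-2, ..., 2\}), so the search-space size is `5 ^ n_params`.
#'
#' @param env A `task_env`.
#' @return List with `weight_slots`, `n_nodes`, `n_params`, and
#'   `log10_size` (the base-10 logarithm of `5 ^ n_params`).
#' @export
search_space_params <- function(env) {
  ls <- env$layer_sizes
  slots <- sum(ls[-length(ls)] * ls[-1L])
  n_nodes <- sum(ls)
  n_params <- slots + n_nodes
  list(weight_slots = slots, n_nodes = n_nodes, n_params = n_params,
       log10_size = n_params * log10(5))
}

#' Random-sampling baseline
#'
#' Samples uniform random genomes (each weight slot one of four values or
#' absent, each threshold one of five values) and returns the best
#' performance found — the baseline showing that high-performing networks
#' are vanishingly rare under random sampling.
#'
#' @param env A `task_env`.
#' @param n_samples Number of random genomes.
#' @param lambda,bias_sign Transfer parameters.
#' @return List with `best_performance` and `best_genome`.
#' @export
random_sampling_baseline <- function(env, n_samples, lambda = 20,
                                     bias_sign = -1) {
  stopifnot(n_samples >= 1)
  best <- -Inf
  best_g <- NULL
  for (i in seq_len(n_samples)) {
    g <- random_genome_for(env)
    p <- performance(g, env, lambda, bias_sign)
    if (p > best) {
      best <- p
      best_g <- g
    }
  }
  list(best_performance = best, best_genome = best_g)
}

#' Survey of random genomes in (cost, Q, performance) space
#'
#' Samples uniform random genomes and measures connection cost,
#' modularity Q of the displayed network, and performance for each — used
#' to show that low-cost networks are more likely to be modular
#' irrespective of performance (negative cost-Q correlation).
#'
#' @param env A `task_env`.
#' @param n_samples Number of random genomes.
#' @param cost_kind Cost function, see [connection_cost()].
#' @param lambda,bias_sign Transfer parameters.
#' @return data.frame with columns `cost`, `q`, `performance`.
#' @export
random_genome_survey <- function(env, n_samples,
                                 cost_kind = c("length_sq", "count"),
                                 lambda = 20, bias_sign = -1) {
  cost_kind <- match.arg(cost_kind)
  res <- lapply(seq_len(n_samples), function(i) {
    g <- random_genome_for(env)
    q <- if (n_connections(g) > 0L) genome_q(g) else NA_real_
    data.frame(cost = connection_cost(g, cost_kind), q = q,
               performance = performance(g, env, lambda, bias_sign))
  })
  do.call(rbind, res)
}

#' Run a batch of independent trials for one treatment
#'
#' Runs `n_trials` independently seeded trials of the configuration and
#' summarizes the final best network of each: performance, both cost
#' kinds, modularity Q, whether the Q-maximizing bipartition separates
#' the task's subproblem inputs (functional split), and whether perfect
#' sub-solution nodes exist for every subproblem.  Medians carry
#' bootstrapped 95% confidence intervals.
#'
#' @param config An `evo_config`; its `seed` acts as the master seed from
#'   which per-trial seeds are derived (see [trial_seeds()]).
#' @param n_trials Number of trials (the full study conditions use 50).
#' @return An object of class `batch_summary` with `trials` (data.frame),
#'   `medians` (list of bootstrap CIs), `best_genomes`, `config`.
#' @export
run_treatment_batch <- function(config, n_trials) {
  stopifnot(n_trials >= 1)
  seeds <- trial_seeds(config$seed, n_trials)
  env0 <- env_at_generation(config, 0L)
  diag_env <- if (length(env0$subproblems) == 2L) env0 else NULL

  rows <- vector("list", n_trials)
  genomes <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    cfg <- config
    cfg$seed <- seeds[t]
    tr <- run_trial(cfg)
    g <- tr$best_genome
    fsplit <- NA
    psub <- NA
    if (!is.null(diag_env) && n_connections(g) > 0L) {
      dg <- displayed_graph(g)
      fsplit <- if (nrow(dg$A) >= 2L)
        functional_split_check(best_bipartition(dg$A)$membership, diag_env)
      else FALSE
      psub <- has_perfect_subsolutions(g, diag_env,
                                       lambda = config$lambda,
                                       bias_sign = config$bias_sign)
    }
    rows[[t]] <- data.frame(
      trial = t, seed = seeds[t],
      performance = tr$final_performance,
      cost_length = tr$final_cost[["length_sq"]],
      cost_count = tr$final_cost[["count"]],
      q = tr$final_q,
      functional_split = fsplit,
      perfect_subsolutions = psub)
    genomes[[t]] <- g
  }
  trials <- do.call(rbind, rows)
  medians <- lapply(trials[c("performance", "cost_length", "cost_count",
                             "q")], function(v) {
    v <- v[!is.na(v)]
    if (length(v)) bootstrap_median_ci(v) else c(median = NA, lo = NA,
                                                 hi = NA)
  })
  structure(list(trials = trials, medians = medians,
                 best_genomes = genomes, config = config),
            class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat("Batch of", nrow(x$trials), "trials,", x$config$treatment,
      "treatment\n")
  for (m in names(x$medians)) {
    ci <- x$medians[[m]]
    cat(sprintf("  %-12s median %.4g  [%.4g, %.4g]\n", m, ci[1L], ci[2L],
                ci[3L]))
  }
  if (!all(is.na(x$trials$functional_split)))
    cat("  functional split:",
        sum(x$trials$functional_split, na.rm = TRUE), "/",
        nrow(x$trials), "trials\n")
  if (!all(is.na(x$trials$perfect_subsolutions)))
    cat("  perfect sub-solutions:",
        sum(x$trials$perfect_subsolutions, na.rm = TRUE), "/",
        nrow(x$trials), "trials\n")
  invisible(x)
}

#' Compare two treatment batches
#'
#' Rank-sum (Mann-Whitney) tests on performance and modularity Q, and
#' Fisher's exact tests on the functional-split and perfect-sub-solution
#' flags, between two batches.
#'
#' @param a,b `batch_summary` objects.
#' @return List of `htest` results (`performance`, `q`,
#'   `functional_split`, `perfect_subsolutions`; the categorical entries
#'   are `NULL` when either batch lacks the flags).
#' @export
compare_batches <- function(a, b) {
  out <- list(
    performance = stats::wilcox.test(a$trials$performance,
                                     b$trials$performance, exact = FALSE),
    q = stats::wilcox.test(a$trials$q, b$trials$q, exact = FALSE))
  for (flag in c("functional_split", "perfect_subsolutions")) {
    fa <- a$trials[[flag]]
    fb <- b$trials[[flag]]
    out[[flag]] <- if (all(is.na(fa)) || all(is.na(fb))) NULL else {
      tab <- rbind(a = table(factor(fa, c(FALSE, TRUE))),
                   b = table(factor(fb, c(FALSE, TRUE))))
      stats::fisher.test(tab)
    }
  }
  out
}

#' Evolvability transfer experiment
#'
#' Takes networks that evolved to perfect performance in a source
#' environment, clones each into a full population, and evolves it in the
#' target environment (keeping the treatment's objectives) until a
#' perfect network appears or `max_generations` pass.  The recorded value
#' per replicate is the first generation at which a network with
#' performance >= `target_performance` exists (0 if the seed network
#' already reaches it); censored replicates enter at `max_generations`.
#'
#' @param seed_genomes List of `network_genome`s (the per-trial best
#'   networks from the source environment).
#' @param target_env The `task_env` to transfer into.
#' @param config An `evo_config` giving treatment, population size and
#'   mutation parameters; its `seed` seeds the replicate streams.
#' @param n_replicates Replicates per seed network (full scale: 50).
#' @param max_generations Censoring horizon (full scale: 5000).
#' @param target_performance Performance counting as adapted
#'   (default 1.0); lower values are used in scaled-down runs.
#' @param require_perfect Error if a seed genome is below
#'   `target_performance` in the *source* sense, i.e. not a perfect
#'   solution?  Default `TRUE`; scaled-down runs may pass `FALSE`.
#' @param source_env Environment used for the `require_perfect` check
#'   (defaults to `target_env`'s sizes; only consulted when checking).
#' @return An object of class `transfer_result`: data.frame with columns
#'   `seed_network`, `replicate`, `generations` (censored at
#'   `max_generations`).
#' @export
evolvability_transfer <- function(seed_genomes, target_env, config,
                                  n_replicates = 50L,
                                  max_generations = 5000L,
                                  target_performance = 1.0,
                                  require_perfect = TRUE,
                                  source_env = NULL) {
  if (require_perfect && !is.null(source_env)) {
    sp <- vapply(seed_genomes, performance, numeric(1), env = source_env,
                 lambda = config$lambda, bias_sign = config$bias_sign)
    if (any(sp < target_performance))
      stop("seed networks must reach target performance in the source ",
           "environment")
  }
  seeds <- trial_seeds(config$seed, length(seed_genomes) * n_replicates)
  tcfg <- config
  tcfg$env <- target_env
  tcfg$generations <- as.integer(max_generations)
  problem <- engine_problem(tcfg)
  params <- engine_params(tcfg, stop_at = target_performance,
                          snap_every = 0L)
  k <- 0L
  rows <- list()
  for (s in seq_along(seed_genomes)) {
    g0 <- seed_genomes[[s]]
    already <- performance(g0, target_env, config$lambda,
                           config$bias_sign) >= target_performance
    init <- list(engine_genome(g0))
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      set.seed(seeds[k])
      gens <- if (already) 0L else {
        res <- .engine_run(problem, params, init)
        if (res$best_perf[res$gens_run] >= target_performance)
          res$gens_run
        else max_generations
      }
      rows[[k]] <- data.frame(seed_network = s, replicate = r,
                              generations = gens)
    }
  }
  structure(list(results = do.call(rbind, rows),
                 max_generations = max_generations,
                 target_performance = target_performance),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  g <- x$results$generations
  cat("Evolvability transfer:", nrow(x$results), "replicates\n")
  cat("  median generations to adapt:", stats::median(g),
      " (censored at", x$max_generations, ":",
      sum(g >= x$max_generations), ")\n")
  invisible(x)
}
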