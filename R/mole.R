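#' Novelty distance of a candidate to an archive
#'
#' Euclidean distance in axis-normalized (cost, Q) space to the nearest
#' archived record.  By default each axis is normalized min-max over the
#' archive's current extent; fixed scales can be supplied instead (the
#' landscape search does so, see [run_mole()] — with extent-relative
#' scales, early archives with little spread on one axis amplify that
#' axis's noise and novelty loses its directional meaning).  An empty
#' archive yields `Inf`.
#'
#' @param cost,q Coordinates of the candidate (scalars or equal-length
#'   vectors, in which case the distance of each candidate is returned).
#' @param archive_cost,archive_q Coordinates of archived records.
#' @param cost_scale,q_scale Optional fixed axis scales (lengths that
#'   count as distance 1).
#' @return Numeric distance(s); `Inf` for an empty archive.
#' @export
novelty_distance <- function(cost, q, archive_cost, archive_q,
                             cost_scale = NULL, q_scale = NULL) {
  if (!length(archive_cost)) return(rep(Inf, length(cost)))
  rx <- if (is.null(cost_scale)) diff(range(archive_cost)) else cost_scale
  ry <- if (is.null(q_scale)) diff(range(archive_q)) else q_scale
  if (rx == 0) rx <- 1
  if (ry == 0) ry <- 1
  vapply(seq_along(cost), function(i) {
    dx <- (cost[i] - archive_cost) / rx
    dy <- (q[i] - archive_q) / ry
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
}

# grid-thin an archive: one best-performance record per cell of an
# n_bins x n_bins grid over the observed (cost, q) ranges
thin_archive <- function(df, genomes, n_bins = 100L) {
  if (!nrow(df)) return(list(df = df, genomes = genomes))
  bin <- function(v) {
    r <- range(v)
    if (r[1L] == r[2L]) return(rep(1L, length(v)))
    pmin(n_bins, 1L + floor((v - r[1L]) / (r[2L] - r[1L]) * n_bins))
  }
  cell <- paste(bin(df$cost), bin(df$q))
  keep <- unlist(lapply(split(seq_len(nrow(df)), cell), function(i)
    i[which.max(df$performance[i])]), use.names = FALSE)
  keep <- sort(keep)
  list(df = df[keep, , drop = FALSE], genomes = genomes[keep])
}

#' Multi-Objective Landscape Exploration (MOLE)
#'
#' Searches for high-performing networks at every combination of
#' connection cost and modularity Q.  An NSGA-II population evolves under
#' two deterministically applied objectives: performance, and novelty
#' (distance in normalized (cost, Q) space to the nearest individual
#' already discovered).  Every evaluated individual enters an archive that
#' is grid-thinned to one best-performance representative per cell;
#' novelty pulls the search towards unexplored regions of the plane while
#' performance pulls each region towards its best attainable score.
#'
#' @param env A `task_env`.
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param cost_kind `"length_sq"` (default) or `"count"`.
#' @param mutation Mutation rates, see [evolution_config()].
#' @param n_bins Archive grid resolution per axis (default 100).
#' @param lambda,bias_sign Transfer parameters.
#' @param seed RNG seed.
#' @return An object of class `mole_archive`: list with `records` (a
#'   data.frame of cost, q, performance) and `genomes`.
#' @export
run_mole <- function(env, pop_size = 100L, generations = 500L,
                     cost_kind = c("length_sq", "count"),
                     mutation = list(), n_bins = 100L,
                     lambda = 20, bias_sign = -1, seed = 1L) {
  cost_kind <- match.arg(cost_kind)
  set.seed(seed)
  config <- evolution_config(env, treatment = "PA", pop_size = pop_size,
                             generations = generations,
                             mutation = mutation,
                             lambda = lambda, bias_sign = bias_sign,
                             seed = seed)

  io <- env$io_coords
  problem <- list(layers = env$layer_sizes, X = env$X,
                  targets = list(env$targets + 0),
                  fixed_x = c(io$input[, 1L], io$output[, 1L]),
                  fixed_y = c(io$input[, 2L], io$output[, 2L]),
                  lambda = lambda, bias_sign = bias_sign)
  measure <- function(genomes) {
    res <- .engine_measure(genomes, problem,
                           if (cost_kind == "length_sq") 0L else 1L)
    data.frame(cost = res[1L, ], q = res[2L, ], performance = res[3L, ])
  }
  mpar <- engine_params(config)

  # fixed novelty scales: Q lives in [0, 1]; the cost axis is scaled by
  # the fully connected architecture (the largest cost a genome can have)
  full <- empty_genome(env)
  for (l in seq_along(full$weights)) full$weights[[l]][] <- 1L
  cost_scale <- if (cost_kind == "length_sq")
    connection_cost(full, "length_sq") else n_connections(full)
  q_scale <- 1

  genomes <- lapply(replicate(pop_size, random_genome_for(env),
                              simplify = FALSE), engine_genome)
  df <- measure(genomes)
  arch <- thin_archive(df, genomes, n_bins)

  pop_g <- genomes
  pop_df <- df
  pop_nov <- rep(0, pop_size)
  for (gen in seq_len(generations)) {
    rc <- .engine_rank_crowd(pop_df$performance, pop_nov, p = 1)
    idx <- select_parents(pop_df$performance, pop_nov, rc$rank, rc$crowd,
                          p = 1, k = pop_size)
    off_g <- .engine_mutate_batch(pop_g[idx], mpar, problem)
    off_df <- measure(off_g)

    # novelty is measured against the archive before the offspring are
    # inserted, so an individual landing in unexplored territory scores
    # high for the selection round in which it was discovered
    all_g <- c(pop_g, off_g)
    all_df <- rbind(pop_df, off_df)
    nov_all <- novelty_distance(all_df$cost, all_df$q,
                                arch$df$cost, arch$df$q,
                                cost_scale = cost_scale,
                                q_scale = q_scale)
    nov_all[!is.finite(nov_all)] <- max(nov_all[is.finite(nov_all)], 1) + 1

    arch <- thin_archive(rbind(arch$df, off_df),
                         c(arch$genomes, off_g), n_bins)

    rc2 <- .engine_rank_crowd(all_df$performance, nov_all, p = 1)
    keep <- order(rc2$rank, -rc2$crowd)[seq_len(pop_size)]
    pop_g <- all_g[keep]
    pop_df <- all_df[keep, , drop = FALSE]
    pop_nov <- nov_all[keep]
  }

  structure(list(records = arch$df,
                 genomes = lapply(arch$genomes, genome_from_engine,
                                  io_coords = env$io_coords),
                 env = env$name, cost_kind = cost_kind, n_bins = n_bins),
            class = "mole_archive")
}

#' @export
print.mole_archive <- function(x, ...) {
  cat("MOLE archive (", x$env, ", cost = ", x$cost_kind, ")\n", sep = "")
  cat("  records:", nrow(x$records), "\n")
  cat("  best performance:", format(max(x$records$performance),
                                    digits = 4), "\n")
  invisible(x)
}

#' Build a landscape map from MOLE archives
#'
#' Bins the merged records of one or more archives onto a fixed
#' (cost, Q) grid and keeps the best performance found per cell — the map
#' of best achievable performance over the cost-modularity plane.
#'
#' @param archives A `mole_archive` or list of them.
#' @param n_bins Grid resolution per axis (default 100).
#' @param cost_range,q_range Optional fixed axis ranges; default is the
#'   union of the archives' extents.
#' @return An object of class `landscape_map`: list with `performance`
#'   (n_bins x n_bins matrix, cost bins in rows), `cost_breaks`,
#'   `q_breaks`.
#' @export
build_landscape_map <- function(archives, n_bins = 100L,
                                cost_range = NULL, q_range = NULL) {
  if (inherits(archives, "mole_archive")) archives <- list(archives)
  if (!length(archives)) stop("need at least one archive")
  rec <- do.call(rbind, lapply(archives, function(a) a$records))
  if (is.null(cost_range)) cost_range <- range(rec$cost)
  if (is.null(q_range)) q_range <- range(rec$q)
  cb <- seq(cost_range[1L], cost_range[2L], length.out = n_bins + 1L)
  qb <- seq(q_range[1L], q_range[2L], length.out = n_bins + 1L)
  bi <- pmin(n_bins, pmax(1L, findInterval(rec$cost, cb,
                                           rightmost.closed = TRUE)))
  bj <- pmin(n_bins, pmax(1L, findInterval(rec$q, qb,
                                           rightmost.closed = TRUE)))
  perf <- matrix(NA_real_, n_bins, n_bins)
  for (k in seq_len(nrow(rec))) {
    cur <- perf[bi[k], bj[k]]
    if (is.na(cur) || rec$performance[k] > cur)
      perf[bi[k], bj[k]] <- rec$performance[k]
  }
  structure(list(performance = perf, cost_breaks = cb, q_breaks = qb),
            class = "landscape_map")
}

#' @export
print.landscape_map <- function(x, ...) {
  filled <- sum(!is.na(x$performance))
  cat("Landscape map:", nrow(x$performance), "x", ncol(x$performance),
      "grid,", filled, "cells filled\n")
  cat("  best performance:", format(max(x$performance, na.rm = TRUE),
                                    digits = 4), "\n")
  invisible(x)
}

#' Heat-map plot of a landscape map
#'
#' @param x A `landscape_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.landscape_map <- function(x, ...) {
  graphics::image(x$cost_breaks, x$q_breaks, x$performance,
                  xlab = "connection cost", ylab = "modularity Q",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Export a landscape map as CSV
#'
#' One row per filled cell: `cost_bin`, `q_bin` (bin midpoints) and
#' `best_performance`.
#'
#' @param map A `landscape_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(map, path) {
  mid <- function(b) (b[-1L] + b[-length(b)]) / 2
  idx <- which(!is.na(map$performance), arr.ind = TRUE)
  df <- data.frame(cost_bin = mid(map$cost_breaks)[idx[, 1L]],
                   q_bin = mid(map$q_breaks)[idx[, 2L]],
                   best_performance = map$performance[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
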