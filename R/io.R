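#' Derive independent per-trial seeds from a master seed
#'
#' A single master seed spawns one seed per trial so trials can be run
#' (or re-run) independently and reproducibly.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds.
#' @return Integer vector of `n` seeds.
#' @export
trial_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

task_from_name <- function(task, objects = NULL) {
  obj <- if (is.null(objects)) retina_object_sets() else objects
  switch(task,
         retina_and = build_retina_environment("and", obj),
         retina_or = build_retina_environment("or", obj),
         retina_nonmodular = build_nonmodular_retina_environment(),
         five_xor = build_xor_environment("five_xor"),
         hierarchical_xor = build_xor_environment("hierarchical_xor"),
         stop("unknown task '", task, "'"))
}

parse_object_sets <- function(x) {
  to_mat <- function(strings) {
    rows <- lapply(strings, function(s) {
      bits <- as.integer(strsplit(as.character(s), "")[[1L]])
      if (length(bits) != 4L || !all(bits %in% 0:1))
        stop("object patterns must be 4-character bit strings")
      bits == 1L
    })
    do.call(rbind, rows)
  }
  list(left = to_mat(x$left), right = to_mat(x$right))
}

#' Load and validate an evolution configuration from YAML
#'
#' Recognized fields: `task` (one of `retina_and`, `retina_or`,
#' `retina_nonmodular`, `five_xor`, `hierarchical_xor`), `treatment`,
#' `p_cost`, `pop_size`, `generations`, `mutation` (add / remove /
#' threshold / weight), `weight_mode`, `sigma`, `seed`, `mvg`
#' (`task_b`, `period`), and `objects` (`left` / `right` lists of
#' 4-character bit strings overriding the retina object sets).  Missing
#' fields take the defaults of [evolution_config()] (p_cost 0.25,
#' population 1000, 25000 generations).  Validation failures report the
#' offending field.
#'
#' @param path Path to a YAML file.
#' @return An `evo_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("task", "treatment", "p_cost", "pop_size", "generations",
             "mutation", "weight_mode", "sigma", "seed", "mvg", "objects")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(raw$task)) stop("field 'task' is required")
  objects <- if (!is.null(raw$objects)) parse_object_sets(raw$objects)
  env <- task_from_name(raw$task, objects)
  if (!is.null(raw$mvg)) {
    if (is.null(raw$mvg$task_b)) stop("field 'mvg.task_b' is required")
    env_b <- task_from_name(raw$mvg$task_b, objects)
    period <- if (is.null(raw$mvg$period)) 20L else raw$mvg$period
    env <- mvg_schedule(env, env_b, period)
  }
  args <- list(env = env)
  for (f in c("treatment", "p_cost", "pop_size", "generations",
              "mutation", "weight_mode", "sigma", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  cfg <- tryCatch(do.call(evolution_config, args),
                  error = function(e) stop("invalid config (", path, "): ",
                                           conditionMessage(e),
                                           call. = FALSE))
  cfg$task <- raw$task
  cfg
}

#' Write an evolution configuration to YAML
#'
#' Writes the scalar fields and mutation rates of a configuration; the
#' task is written by name when the config was built by [load_config()].
#'
#' @param config An `evo_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- list(
    task = config$task,
    treatment = config$treatment,
    p_cost = config$p_cost,
    pop_size = config$pop_size,
    generations = config$generations,
    mutation = config$mutation,
    weight_mode = config$weight_mode,
    sigma = config$sigma,
    seed = config$seed)
  if (inherits(config$env, "mvg_schedule"))
    out$mvg <- list(period = config$env$period)
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- genome serialization ---------------------------------------------------

#' Serialize a genome to JSON
#'
#' Stores layer sizes, present connections as (layer, source, target,
#' weight) triplets, per-layer thresholds, mode, and I/O coordinates.
#'
#' @param genome A `network_genome`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_genome_json <- function(genome, path = NULL) {
  conns <- list()
  for (l in seq_along(genome$weights)) {
    idx <- which(genome$weights[[l]] != 0, arr.ind = TRUE)
    if (nrow(idx))
      conns[[length(conns) + 1L]] <-
        data.frame(layer = l, source = idx[, 1L], target = idx[, 2L],
                   weight = genome$weights[[l]][idx])
  }
  obj <- list(
    layers = genome$layers,
    mode = if (is.null(genome$mode)) "integer" else genome$mode,
    connections = if (length(conns)) do.call(rbind, conns)
    else data.frame(layer = integer(0), source = integer(0),
                    target = integer(0), weight = numeric(0)),
    thresholds = genome$thresholds,
    io_coords = if (is.null(genome$io_coords)) NULL else
      list(input = unname(as.matrix(genome$io_coords$input)),
           output = unname(as.matrix(genome$io_coords$output))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a genome from JSON
#'
#' Inverse of [write_genome_json()].
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A `network_genome`.
#' @export
read_genome_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  ls <- as.integer(obj$layers)
  W <- lapply(seq_len(length(ls) - 1L), function(l)
    matrix(0, ls[l], ls[l + 1L]))
  cn <- obj$connections
  if (length(cn) && nrow(cn)) {
    for (k in seq_len(nrow(cn))) {
      W[[cn$layer[k]]][cn$source[k], cn$target[k]] <- cn$weight[k]
    }
  }
  io <- NULL
  if (!is.null(obj$io_coords)) {
    io <- list(input = as.matrix(obj$io_coords$input),
               output = as.matrix(obj$io_coords$output))
  }
  network_genome(ls, W, obj$thresholds, io,
                 mode = if (is.null(obj$mode)) "integer" else obj$mode)
}

#' Export a network to GraphML, DOT or JSON
#'
#' Writes the displayed network (connectionless nodes omitted) with node
#' attributes for layer, role, optimally placed coordinates and, if
#' given, module membership.
#'
#' @param genome A `network_genome`.
#' @param path Output path.
#' @param format `"graphml"`, `"dot"` or `"json"`.
#' @param partition Optional named module assignment (e.g.
#'   `genome_modularity(g)$membership`).
#' @param placement Optional [optimal_placement()] result (computed on
#'   demand when the genome has coordinates).
#' @return `path`, invisibly.
#' @export
export_network <- function(genome, path,
                           format = c("graphml", "dot", "json"),
                           partition = NULL, placement = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    write_genome_json(genome, path)
    return(invisible(path))
  }
  if (is.null(placement) && !is.null(genome$io_coords))
    placement <- optimal_placement(genome)
  g <- as_igraph_genome(genome, partition, placement)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Run manifest: reproducible record of a batch
#'
#' Captures the configuration snapshot, master seed, derived per-trial
#' seeds, package version, and output paths; re-running a manifest
#' reproduces all deterministic outputs.
#'
#' @param config An `evo_config`.
#' @param n_trials Number of trials the manifest covers.
#' @param out_dir Output directory recorded in the manifest.
#' @param path Optional path to also write the manifest as JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, n_trials, out_dir = ".", path = NULL) {
  man <- list(
    package = "modcost",
    version = as.character(utils::packageVersion("modcost")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    treatment = config$treatment,
    env = if (inherits(config$env, "mvg_schedule"))
      paste0("MVG:", config$env$envs[[1L]]$name, "<->",
             config$env$envs[[2L]]$name, ":E", config$env$period)
    else config$env$name,
    p_cost = config$p_cost,
    pop_size = config$pop_size,
    generations = config$generations,
    mutation = config$mutation,
    weight_mode = config$weight_mode,
    master_seed = config$seed,
    trial_seeds = trial_seeds(config$seed, n_trials),
    out_dir = out_dir)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}
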