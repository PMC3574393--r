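#' @keywords internal
# All binary patterns of a given width, as a logical matrix (one pattern per
# row).  Bit 1 is the leftmost input.  Rows are ordered by the integer value
# of the pattern read left-to-right (0 ... 2^width - 1).
all_patterns <- function(width) {
  n <- 2L^width
  m <- matrix(FALSE, n, width)
  v <- 0:(n - 1L)
  for (j in seq_len(width)) {
    m[, j] <- bitwAnd(v, bitwShiftL(1L, width - j)) != 0L
  }
  m
}

#' Encode binary patterns as network inputs
#'
#' ON pixels map to +1 and OFF to -1 by default (matching the node output
#' range); `encoding = "01"` maps to 1/0.
#'
#' @param patterns Logical matrix (patterns x inputs).
#' @param encoding `"pm1"` (default) or `"01"`.
#' @return Numeric matrix of input activations.
#' @export
encode_patterns <- function(patterns, encoding = c("pm1", "01")) {
  encoding <- match.arg(encoding)
  if (encoding == "pm1") ifelse(patterns, 1, -1) else patterns + 0
}

#' Default retina object sets
#'
#' The retina task shows an 8-pixel pattern split into a left and a right
#' half of 4 pixels; each half may contain an "object", a 4-pixel pattern
#' of interest.  Eight of the sixteen possible half-patterns count as
#' objects on each side, with slightly different sets for the two sides:
#' a half-pattern is an object if at least three pixels are ON, or exactly
#' two pixels are ON including the outer (edge) pixel of that half.  The
#' sets are mirror images of each other and are overridable (e.g. via a
#' YAML config, see [load_config()]).
#'
#' @return List with logical matrices `left` and `right` (8 x 4 each), one
#'   object pattern per row.
#' @export
retina_object_sets <- function() {
  p4 <- all_patterns(4L)
  k <- rowSums(p4)
  left <- p4[k >= 3 | (k == 2 & p4[, 1L]), , drop = FALSE]
  right <- p4[k >= 3 | (k == 2 & p4[, 4L]), , drop = FALSE]
  list(left = left, right = right)
}

# membership test: which rows of `patterns` appear in `set`
pattern_in_set <- function(patterns, set) {
  key <- function(m) apply(m, 1L, function(r) paste(as.integer(r), collapse = ""))
  key(patterns) %in% key(set)
}

new_task_env <- function(name, patterns, targets, subproblems, combine,
                         layer_sizes, io_coords, encoding = "pm1") {
  structure(list(
    name = name,
    patterns = patterns,
    X = encode_patterns(patterns, encoding),
    targets = targets,
    subproblems = subproblems,
    combine = combine,
    layer_sizes = as.integer(layer_sizes),
    io_coords = io_coords,
    encoding = encoding
  ), class = "task_env")
}

#' @export
print.task_env <- function(x, ...) {
  cat("Task environment:", x$name, "\n")
  cat("  patterns:", nrow(x$patterns), " inputs:", ncol(x$patterns),
      " outputs:", ncol(x$targets), "\n")
  cat("  layers:  ", paste(x$layer_sizes, collapse = "-"), "\n")
  if (length(x$subproblems))
    cat("  subproblems:", length(x$subproblems), "\n")
  invisible(x)
}

retina_io_coords <- function() {
  list(input = cbind(x = seq(-3.5, 3.5, by = 1), y = 0),
       output = cbind(x = 4, y = 0))
}

#' Build a retina environment (L-AND-R or L-OR-R)
#'
#' All 256 8-pixel patterns are enumerated.  The target answer is whether
#' an object is present on both halves (`"and"`) or on either half
#' (`"or"`).  The left and right object-detection subproblems are recorded
#' as decomposition metadata for functional-modularity diagnostics.
#'
#' Network architecture: 8 inputs at x = -3.5 ... 3.5 (y = 0), hidden
#' layers of at most 8/4/2 nodes, one output at (4, 0).
#'
#' @param mode `"and"` or `"or"`.
#' @param objects Object sets as returned by [retina_object_sets()].
#' @param encoding Input encoding, see [encode_patterns()].
#' @return A `task_env`.
#' @export
build_retina_environment <- function(mode = c("and", "or"),
                                     objects = retina_object_sets(),
                                     encoding = "pm1") {
  mode <- match.arg(mode)
  p <- all_patterns(8L)
  left_obj <- pattern_in_set(p[, 1:4, drop = FALSE], objects$left)
  right_obj <- pattern_in_set(p[, 5:8, drop = FALSE], objects$right)
  tgt <- if (mode == "and") left_obj & right_obj else left_obj | right_obj
  subproblems <- list(
    list(name = "left", inputs = 1:4, answers = left_obj),
    list(name = "right", inputs = 5:8, answers = right_obj))
  new_task_env(paste0("retina-", toupper(mode)), p,
               matrix(tgt, ncol = 1L), subproblems, mode,
               c(8L, 8L, 4L, 2L, 1L), retina_io_coords(), encoding)
}

#' Build the non-modular retina environment
#'
#' The target is whether at least four of the eight pixels are ON
#' (`predicate = "at_least_4"`, default) or exactly four
#' (`"exactly_4"`).  The answer needs information from every input, so the
#' task has no left/right decomposition and carries no subproblem
#' metadata.
#'
#' @param predicate Counting rule for the target.
#' @param encoding Input encoding.
#' @return A `task_env`.
#' @export
build_nonmodular_retina_environment <- function(
    predicate = c("at_least_4", "exactly_4"), encoding = "pm1") {
  predicate <- match.arg(predicate)
  p <- all_patterns(8L)
  k <- rowSums(p)
  tgt <- if (predicate == "at_least_4") k >= 4 else k == 4
  new_task_env("retina-nonmodular", p, matrix(tgt, ncol = 1L), list(),
               "none", c(8L, 8L, 4L, 2L, 1L), retina_io_coords(), encoding)
}

#' Build an XOR environment
#'
#' Two fully separable Boolean tasks:
#' \describe{
#'   \item{`five_xor`}{10 inputs, 5 outputs; output k is the XOR of the
#'     consecutive input pair (2k-1, 2k).  1024 patterns, one hidden layer
#'     of at most 8 nodes.  Inputs at x = -4.5 ... 4.5 (y = 0), outputs at
#'     x = -4, -2, 0, 2, 4 (y = 2).}
#'   \item{`hierarchical_xor`}{8 inputs, 2 outputs; each output is the XOR
#'     of the XORs of its half's two input pairs.  256 patterns, hidden
#'     layers of at most 8/4/4 nodes.  Inputs at x = -3.5 ... 3.5 (y = 0),
#'     outputs at x = -2, 2 (y = 4).}
#' }
#' XOR is true iff its two arguments differ.
#'
#' @param kind `"five_xor"` or `"hierarchical_xor"`.
#' @param encoding Input encoding.
#' @return A `task_env`.
#' @export
build_xor_environment <- function(kind = c("five_xor", "hierarchical_xor"),
                                  encoding = "pm1") {
  kind <- match.arg(kind)
  if (kind == "five_xor") {
    p <- all_patterns(10L)
    tgt <- sapply(1:5, function(k) xor(p[, 2L * k - 1L], p[, 2L * k]))
    subproblems <- lapply(1:5, function(k)
      list(name = paste0("xor", k), inputs = c(2L * k - 1L, 2L * k),
           answers = tgt[, k]))
    io <- list(input = cbind(x = seq(-4.5, 4.5, by = 1), y = 0),
               output = cbind(x = c(-4, -2, 0, 2, 4), y = 2))
    new_task_env("five-xor", p, tgt, subproblems, "parallel",
                 c(10L, 8L, 5L), io, encoding)
  } else {
    p <- all_patterns(8L)
    h1 <- xor(xor(p[, 1L], p[, 2L]), xor(p[, 3L], p[, 4L]))
    h2 <- xor(xor(p[, 5L], p[, 6L]), xor(p[, 7L], p[, 8L]))
    tgt <- cbind(h1, h2)
    subproblems <- list(
      list(name = "left-half", inputs = 1:4, answers = h1),
      list(name = "right-half", inputs = 5:8, answers = h2))
    io <- list(input = cbind(x = seq(-3.5, 3.5, by = 1), y = 0),
               output = cbind(x = c(-2, 2), y = 4))
    new_task_env("hierarchical-xor", p, tgt, subproblems, "xor",
                 c(8L, 8L, 4L, 4L, 2L), io, encoding)
  }
}

#' Fraction of correct answers of a genome on an environment
#'
#' Evaluates the network on every pattern of the environment and returns
#' the fraction of (pattern, output) pairs whose classified answer
#' (output >= 0 is true) equals the target.
#'
#' @param genome A `network_genome` whose I/O sizes match the environment.
#' @param env A `task_env`.
#' @param lambda,bias_sign Transfer parameters, see [node_output()].
#' @return Scalar in \[0, 1\].
#' @export
performance <- function(genome, env, lambda = 20, bias_sign = -1) {
  if (genome$layers[1L] != ncol(env$patterns) ||
      genome$layers[length(genome$layers)] != ncol(env$targets))
    stop("genome I/O sizes do not match environment")
  out <- network_outputs(genome, env$X, lambda, bias_sign)
  mean(classify(out) == env$targets)
}

#' Construct a genome skeleton matching an environment
#'
#' @param env A `task_env`.
#' @return An unconnected `network_genome` with the environment's layer
#'   sizes and fixed I/O coordinates.
#' @export
empty_genome <- function(env) {
  network_genome(env$layer_sizes, io_coords = env$io_coords)
}

#' Random genome matching an environment
#'
#' @param env A `task_env`.
#' @return A `network_genome`, see [random_genome()].
#' @export
random_genome_for <- function(env) {
  random_genome(env$layer_sizes, env$io_coords)
}

#' Modularly-varying-goals schedule
#'
#' Alternates deterministically between two environments sharing
#' subproblems (classically L-AND-R and L-OR-R), switching every `period`
#' generations.
#'
#' @param env_a,env_b The two `task_env`s (must have identical I/O sizes).
#' @param period Switch period E in generations, >= 1.
#' @return An object of class `mvg_schedule`.
#' @export
mvg_schedule <- function(env_a, env_b, period = 20L) {
  stopifnot(period >= 1,
            identical(env_a$layer_sizes, env_b$layer_sizes))
  structure(list(envs = list(env_a, env_b), period = as.integer(period)),
            class = "mvg_schedule")
}

#' Environment active at a given generation
#'
#' @param schedule An `mvg_schedule`.
#' @param generation Generation index, >= 0.
#' @return The active `task_env`.
#' @export
environment_at <- function(schedule, generation) {
  stopifnot(generation >= 0)
  idx <- (generation %/% schedule$period) %% 2L
  schedule$envs[[idx + 1L]]
}

#' Randomize input coordinates within the input row
#'
#' Applies a uniform random permutation to the input nodes' x-values
#' (their y-values and the output coordinates stay fixed).  Used by the
#' randomized-coordinates control treatment, which tests whether
#' modularity under a wiring-length cost depends on the inputs of
#' different subproblems being geometrically adjacent.  Draws from the
#' current RNG stream.
#'
#' @param env A `task_env`.
#' @return The environment with permuted input x-coordinates.
#' @export
randomize_input_coords <- function(env) {
  n <- nrow(env$io_coords$input)
  perm <- sample.int(n)
  env$io_coords$input[, 1L] <- env$io_coords$input[perm, 1L]
  env
}

#' Export an environment truth table as CSV
#'
#' One row per pattern: input bits (0/1) then one target column per
#' output.
#'
#' @param env A `task_env`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(env, path) {
  df <- data.frame(env$patterns + 0)
  names(df) <- paste0("in", seq_len(ncol(env$patterns)))
  t <- data.frame(env$targets + 0)
  names(t) <- paste0("target", seq_len(ncol(env$targets)))
  utils::write.csv(cbind(df, t), path, row.names = FALSE)
  invisible(path)
}
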