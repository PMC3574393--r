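#' Layered feed-forward network genome
#'
#' A genome describes a feed-forward network whose nodes are arranged in
#' layers; connections only link consecutive layers.  Connection weights are
#' the integers \{-2, -1, 1, 2\} (0 encodes "no connection") and every node
#' carries an integer threshold (bias) in \{-2, ..., 2\}.  Input and output
#' nodes sit at fixed 2-D coordinates; hidden nodes are free and are placed
#' by [optimal_placement()] when wiring length is costed.
#'
#' Weights are stored as a list of dense matrices, one per consecutive layer
#' pair: `weights[[l]][i, j]` is the weight from node `i` of layer `l` to
#' node `j` of layer `l + 1`.  Thresholds are stored for every node,
#' including inputs; input thresholds are inert during evaluation but are
#' part of the evolvable parameter set (see [search_space_params()]).
#'
#' @param layer_sizes Integer vector of node counts per layer
#'   (inputs, hidden ..., outputs).  At least two layers, all sizes >= 1.
#' @param weights List of weight matrices, or `NULL` for an unconnected
#'   genome.
#' @param thresholds List of integer vectors (one per layer), or `NULL` for
#'   all-zero thresholds.
#' @param io_coords List with elements `input` and `output`, each a
#'   two-column matrix of node coordinates.  `NULL` leaves the genome
#'   without geometry (only needed for length costs and plotting).
#' @param mode `"integer"` (default) for the four-value weight alphabet, or
#'   `"real"` for real-valued weights and thresholds in \[-2, 2\] (mutated
#'   by Gaussian perturbation, see [mutate()]).
#' @return An object of class `network_genome`.
#' @seealso [evaluate_network()], [random_genome()], [mutate()]
#' @export
network_genome <- function(layer_sizes, weights = NULL, thresholds = NULL,
                           io_coords = NULL, mode = c("integer", "real")) {
  mode <- match.arg(mode)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L))
    stop("need >= 2 layers, all sizes >= 1")
  L <- length(layer_sizes)
  if (is.null(weights)) {
    weights <- lapply(seq_len(L - 1L), function(l)
      matrix(0L, layer_sizes[l], layer_sizes[l + 1L]))
  }
  if (is.null(thresholds)) {
    thresholds <- lapply(layer_sizes, function(n) integer(n))
  }
  cast <- if (mode == "integer") {
    function(x) { storage.mode(x) <- "integer"; x }
  } else {
    function(x) { storage.mode(x) <- "double"; x }
  }
  g <- structure(list(
    layers = layer_sizes,
    weights = lapply(weights, cast),
    thresholds = lapply(thresholds, function(b) cast(b)),
    io_coords = io_coords,
    mode = mode
  ), class = "network_genome")
  validate_genome(g)
  g
}

#' Validate a network genome
#'
#' Checks the structural invariants: weight matrices link consecutive layers
#' with matching dimensions, weights lie in \{-2, -1, 0, 1, 2\} (0 = absent),
#' and thresholds lie in \{-2, ..., 2\}.
#'
#' @param genome A `network_genome`.
#' @return The genome, invisibly.  Errors on violation.
#' @export
validate_genome <- function(genome) {
  ls <- genome$layers
  L <- length(ls)
  integer_mode <- is.null(genome$mode) || genome$mode == "integer"
  stopifnot(length(genome$weights) == L - 1L,
            length(genome$thresholds) == L)
  for (l in seq_len(L - 1L)) {
    w <- genome$weights[[l]]
    if (!all(dim(w) == c(ls[l], ls[l + 1L])))
      stop("weight matrix ", l, " has wrong dimensions")
    if (integer_mode) {
      if (!all(w %in% (-2L):2L))
        stop("weights must be integers in {-2,...,2} (0 = absent)")
    } else if (any(abs(w) > 2)) {
      stop("real-mode weights must lie in [-2, 2]")
    }
  }
  for (l in seq_len(L)) {
    b <- genome$thresholds[[l]]
    if (length(b) != ls[l])
      stop("need one threshold per node")
    if (integer_mode) {
      if (!all(b %in% (-2L):2L))
        stop("thresholds must be integers in {-2,...,2}")
    } else if (any(abs(b) > 2)) {
      stop("real-mode thresholds must lie in [-2, 2]")
    }
  }
  if (!is.null(genome$io_coords)) {
    stopifnot(nrow(genome$io_coords$input) == ls[1L],
              nrow(genome$io_coords$output) == ls[L])
  }
  invisible(genome)
}

#' Single-node transfer function
#'
#' Computes `tanh(lambda * (sum(w * y) - b))`: a sigmoidal threshold unit
#' whose output lies in \[-1, 1\].  The threshold `b` is the input value at
#' which the output transitions from negative to positive; `lambda`
#' (default 20) sets the slope of that transition, so with the default the
#' unit is close to a hard threshold.  With `bias_sign = +1` the bias is
#' added instead of subtracted.
#'
#' @param weights Numeric vector of incoming connection weights (may be
#'   empty).
#' @param inputs Numeric vector of presynaptic outputs, same length.
#' @param threshold Scalar threshold (bias) of the node.
#' @param lambda Transfer slope, > 0.
#' @param bias_sign `-1` (default, subtract threshold) or `+1`.
#' @return Scalar in \[-1, 1\].
#' @examples
#' node_output(numeric(0), numeric(0), 0)   # 0
#' node_output(2, 1, 0)                     # ~ 1 (saturated)
#' @export
node_output <- function(weights, inputs, threshold, lambda = 20,
                        bias_sign = -1) {
  stopifnot(length(weights) == length(inputs), lambda > 0)
  tanh(lambda * (sum(weights * inputs) + bias_sign * threshold))
}

#' Evaluate a network on one or many input patterns
#'
#' Information flows through the network one layer per discrete time step.
#' Nodes with no incoming connections emit the transfer function of an empty
#' sum (i.e. `tanh(-lambda * b)`).
#'
#' @param genome A `network_genome`.
#' @param patterns Numeric vector (one pattern) or matrix with one pattern
#'   per row; values are the input-node activations (conventionally +1 for
#'   ON pixels and -1 for OFF, see [encode_patterns()]).
#' @param lambda,bias_sign Transfer-function parameters, see
#'   [node_output()].
#' @return A list of activation matrices, one per layer (patterns in rows);
#'   element 1 is the input itself, the last element the output-layer
#'   activations.
#' @export
evaluate_network <- function(genome, patterns, lambda = 20, bias_sign = -1) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1L)
  if (ncol(patterns) != genome$layers[1L])
    stop("pattern length ", ncol(patterns), " does not match input layer size ",
         genome$layers[1L])
  L <- length(genome$layers)
  acts <- vector("list", L)
  acts[[1L]] <- patterns
  np <- nrow(patterns)
  for (l in 2L:L) {
    s <- acts[[l - 1L]] %*% genome$weights[[l - 1L]]
    b <- genome$thresholds[[l]]
    acts[[l]] <- tanh(lambda * (s + rep(bias_sign * b, each = np)))
  }
  acts
}

#' Network outputs for a set of patterns
#'
#' Convenience wrapper around [evaluate_network()] returning only the
#' output-layer activations.
#'
#' @inheritParams evaluate_network
#' @return Matrix of output activations (patterns x outputs).
#' @export
network_outputs <- function(genome, patterns, lambda = 20, bias_sign = -1) {
  acts <- evaluate_network(genome, patterns, lambda, bias_sign)
  acts[[length(acts)]]
}

#' Classify a continuous node output as a Boolean answer
#'
#' An output value >= 0 answers true, < 0 answers false.
#'
#' @param value Numeric vector (or matrix) of node outputs.
#' @return Logical of the same shape.
#' @export
classify <- function(value) value >= 0

#' Number of connections in a genome
#'
#' @param genome A `network_genome`.
#' @return Integer count of present (non-zero-weight) connections.
#' @export
n_connections <- function(genome) {
  sum(vapply(genome$weights, function(w) sum(w != 0L), integer(1)))
}

#' Randomly generated genome
#'
#' Samples every weight slot uniformly from \{absent, -2, -1, 1, 2\} and
#' every threshold uniformly from \{-2, ..., 2\}, matching the uniform
#' accounting of the search space (each of the `P` parameters takes one of
#' five values).  Used both to seed evolutionary runs and as the
#' random-sampling baseline.
#'
#' @param layer_sizes Integer vector of layer sizes.
#' @param io_coords Optional fixed input/output coordinates.
#' @return A `network_genome`.
#' @export
random_genome <- function(layer_sizes, io_coords = NULL) {
  L <- length(layer_sizes)
  weights <- lapply(seq_len(L - 1L), function(l) {
    matrix(sample(c(0L, -2L, -1L, 1L, 2L),
                  layer_sizes[l] * layer_sizes[l + 1L], replace = TRUE),
           layer_sizes[l], layer_sizes[l + 1L])
  })
  thresholds <- lapply(layer_sizes, function(n)
    sample((-2L):2L, n, replace = TRUE))
  network_genome(layer_sizes, weights, thresholds, io_coords)
}

# ---- node bookkeeping -------------------------------------------------------

#' Node table for a genome
#'
#' Enumerates all nodes with their layer, within-layer index, a stable
#' label, and connection degree.  Nodes without any connection are flagged:
#' by convention they are excluded from displayed networks and from
#' modularity graphs.
#'
#' @param genome A `network_genome`.
#' @return A data.frame with columns `id`, `layer`, `index`, `label`,
#'   `role` (input/hidden/output), `degree`, `displayed`.
#' @export
node_table <- function(genome) {
  ls <- genome$layers
  L <- length(ls)
  layer <- rep(seq_len(L), ls)
  index <- unlist(lapply(ls, seq_len))
  role <- ifelse(layer == 1L, "input", ifelse(layer == L, "output", "hidden"))
  label <- paste0(c(input = "I", hidden = "H", output = "O")[role],
                  ifelse(role == "hidden", paste0(layer - 1L, ".", index),
                         index))
  deg <- numeric(sum(ls))
  off <- c(0L, cumsum(ls))
  for (l in seq_len(L - 1L)) {
    w <- genome$weights[[l]] != 0L
    deg[off[l] + seq_len(ls[l])] <- deg[off[l] + seq_len(ls[l])] + rowSums(w)
    deg[off[l + 1L] + seq_len(ls[l + 1L])] <-
      deg[off[l + 1L] + seq_len(ls[l + 1L])] + colSums(w)
  }
  data.frame(id = seq_len(sum(ls)), layer = layer, index = index,
             label = label, role = role, degree = deg,
             displayed = deg > 0, stringsAsFactors = FALSE)
}

#' Directed adjacency matrix of the displayed network
#'
#' Builds the 0/1 adjacency matrix over displayed nodes (those with at
#' least one connection), edges directed from earlier to later layers.
#'
#' @param genome A `network_genome`.
#' @return List with `A` (adjacency matrix, row -> column), and `nodes`
#'   (the corresponding subset of [node_table()]).
#' @export
displayed_graph <- function(genome) {
  nt <- node_table(genome)
  ls <- genome$layers
  off <- c(0L, cumsum(ls))
  n <- sum(ls)
  A <- matrix(0L, n, n, dimnames = list(nt$label, nt$label))
  for (l in seq_along(genome$weights)) {
    w <- genome$weights[[l]] != 0L
    A[off[l] + seq_len(ls[l]), off[l + 1L] + seq_len(ls[l + 1L])] <- w + 0L
  }
  keep <- nt$displayed
  list(A = A[keep, keep, drop = FALSE], nodes = nt[keep, , drop = FALSE])
}

#' Convert a genome to an igraph object
#'
#' Connectionless nodes are omitted.  Node attributes carry layer, role,
#' coordinates (from `placement` if given, otherwise fixed I/O coordinates
#' only) and optionally a module assignment.
#'
#' @param genome A `network_genome`.
#' @param partition Optional named integer vector (node label -> module).
#' @param placement Optional result of [optimal_placement()].
#' @return An `igraph` directed graph.
#' @export
as_igraph_genome <- function(genome, partition = NULL, placement = NULL) {
  dg <- displayed_graph(genome)
  g <- igraph::graph_from_adjacency_matrix(dg$A, mode = "directed")
  igraph::V(g)$layer <- dg$nodes$layer
  igraph::V(g)$role <- dg$nodes$role
  if (!is.null(placement)) {
    xy <- placement$coords[dg$nodes$id, , drop = FALSE]
    igraph::V(g)$x <- xy[, 1L]
    igraph::V(g)$y <- xy[, 2L]
  }
  if (!is.null(partition)) {
    igraph::V(g)$module <- as.integer(partition[dg$nodes$label])
  }
  g
}

#' @export
print.network_genome <- function(x, ...) {
  cat("Feed-forward network genome\n")
  cat("  layers:     ", paste(x$layers, collapse = "-"), "\n")
  cat("  connections:", n_connections(x), "\n")
  nt <- node_table(x)
  cat("  displayed nodes:", sum(nt$displayed), "of", nrow(nt), "\n")
  invisible(x)
}

#' Plot a network genome
#'
#' Draws the displayed network at its optimally placed coordinates (inputs
#' and outputs fixed), optionally colouring nodes by module membership.
#'
#' @param x A `network_genome` with I/O coordinates.
#' @param partition Optional named module assignment, e.g. from
#'   [best_bipartition()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.network_genome <- function(x, partition = NULL, ...) {
  if (is.null(x$io_coords)) stop("genome has no I/O coordinates")
  pl <- optimal_placement(x)
  dg <- displayed_graph(x)
  xy <- pl$coords[dg$nodes$id, , drop = FALSE]
  graphics::plot(xy, type = "n", xlab = "x", ylab = "y", asp = 1, ...)
  ed <- which(dg$A != 0L, arr.ind = TRUE)
  graphics::segments(xy[ed[, 1L], 1L], xy[ed[, 1L], 2L],
                     xy[ed[, 2L], 1L], xy[ed[, 2L], 2L], col = "grey60")
  col <- "steelblue"
  if (!is.null(partition)) {
    m <- as.integer(partition[dg$nodes$label])
    col <- c("tomato", "steelblue", "goldenrod", "seagreen")[
      ((m - 1L) %% 4L) + 1L]
  }
  graphics::points(xy, pch = 21, bg = col, cex = 1.6)
  invisible(pl)
}
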