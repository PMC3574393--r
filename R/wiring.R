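#' Optimal placement of hidden nodes
#'
#' Before a wiring-length cost is computed, hidden nodes are placed at the
#' 2-D positions that minimize the summed squared Euclidean length of all
#' connections, holding input and output coordinates fixed.  The objective
#' is quadratic and separable per axis; at the minimum every free node sits
#' at the arithmetic mean of its graph neighbours' positions, which is
#' solved directly as a linear system (the graph-Laplacian equations
#' restricted to free nodes).  Connected components containing no fixed
#' node contribute no determinate position: their members are placed at
#' the centroid of the fixed I/O coordinates (they are functionally
#' isolated from the I/O and contribute no cost through fixed nodes).
#'
#' @param genome A `network_genome` with I/O coordinates.
#' @return List of class `placement_solution` with `coords` (matrix, one
#'   row per node of [node_table()]) and `cost` (total squared length).
#' @export
optimal_placement <- function(genome) {
  if (is.null(genome$io_coords)) stop("genome has no I/O coordinates")
  ls <- genome$layers
  L <- length(ls)
  n <- sum(ls)
  off <- c(0L, cumsum(ls))

  # undirected adjacency over all nodes (edge = present connection)
  A <- matrix(0, n, n)
  for (l in seq_len(L - 1L)) {
    w <- genome$weights[[l]] != 0L
    A[off[l] + seq_len(ls[l]), off[l + 1L] + seq_len(ls[l + 1L])] <- w + 0
  }
  A <- A + t(A)

  fixed <- c(rep(TRUE, ls[1L]), rep(FALSE, n - ls[1L] - ls[L]),
             rep(TRUE, ls[L]))
  xy <- matrix(NA_real_, n, 2L)
  xy[seq_len(ls[1L]), ] <- genome$io_coords$input[, 1:2, drop = FALSE]
  xy[off[L] + seq_len(ls[L]), ] <- genome$io_coords$output[, 1:2, drop = FALSE]
  centroid <- colMeans(xy[fixed, , drop = FALSE])

  free <- which(!fixed)
  if (length(free)) {
    deg <- rowSums(A)
    # free nodes in components not touching a fixed node -> centroid
    reach <- fixed
    repeat {
      nxt <- reach | (A %*% reach > 0)
      if (all(nxt == reach)) break
      reach <- nxt
    }
    stranded <- free[!reach[free]]
    if (length(stranded))
      xy[stranded, ] <- matrix(centroid, length(stranded), 2L, byrow = TRUE)
    solv <- free[reach[free]]
    if (length(solv)) {
      Lap <- diag(deg[solv], nrow = length(solv)) -
        A[solv, solv, drop = FALSE]
      anchored <- which(fixed | !reach)  # stranded already placed
      rhs <- A[solv, anchored, drop = FALSE] %*% xy[anchored, , drop = FALSE]
      xy[solv, ] <- solve(Lap, rhs)
    }
  }

  ed <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  cost <- if (nrow(ed)) {
    d <- xy[ed[, 1L], , drop = FALSE] - xy[ed[, 2L], , drop = FALSE]
    sum(d * d)
  } else 0
  structure(list(coords = xy, cost = cost), class = "placement_solution")
}

#' @export
print.placement_solution <- function(x, ...) {
  cat("Optimal placement: total squared length =", format(x$cost), "\n")
  invisible(x)
}

#' Connection cost of a genome
#'
#' Two cost functions: `"length_sq"`, the summed squared connection length
#' with hidden nodes optimally placed (see [optimal_placement()]); and
#' `"count"`, the number of connections.  A connection counts once
#' regardless of its weight magnitude.
#'
#' @param genome A `network_genome`.
#' @param kind `"length_sq"` (default) or `"count"`.
#' @return Non-negative scalar.
#' @export
connection_cost <- function(genome, kind = c("length_sq", "count")) {
  kind <- match.arg(kind)
  switch(kind,
         length_sq = optimal_placement(genome)$cost,
         count = n_connections(genome))
}
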