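#' Modularity matrix of a directed graph
#'
#' For a directed graph with adjacency `A` (m edges), the contribution of
#' the ordered node pair (i, j) to modularity is
#' `B[i,j] = A[i,j]/m - kout[i]*kin[j]/m^2`; Q for a partition is the sum
#' of `B[i,j]` over pairs in the same module.  With `directed = FALSE` the
#' graph is symmetrized first and the classic undirected form
#' `B[i,j] = A[i,j]/(2m) - k[i]*k[j]/(2m)^2` is used.
#'
#' @param A Square 0/1 adjacency matrix (row = source, column = target).
#' @param directed Use the directed formula (default) or symmetrize.
#' @return The modularity contribution matrix `B`.
#' @keywords internal
q_matrix <- function(A, directed = TRUE) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  m <- sum(A)
  if (m == 0) stop("modularity is undefined for a graph with no edges")
  if (directed) {
    A / m - outer(rowSums(A), colSums(A)) / m^2
  } else {
    As <- A + t(A)
    two_m <- sum(As)
    k <- rowSums(As)
    As / two_m - outer(k, k) / two_m^2
  }
}

#' Directed modularity Q of a partition
#'
#' Q measures the excess of within-module edges over the number expected
#' for random graphs with the same in/out degree sequence, normalized by
#' the edge count; Q <= 1, and the trivial single-module partition always
#' scores 0.
#'
#' @param A Square 0/1 adjacency matrix.
#' @param membership Integer vector of module labels, one per node.
#' @param directed Use the directed formula (default).
#' @return Scalar Q.
#' @export
modularity_q <- function(A, membership, directed = TRUE) {
  B <- q_matrix(A, directed)
  if (length(membership) != nrow(B))
    stop("membership length must equal node count")
  same <- outer(membership, membership, "==")
  sum(B[same])
}

new_modularity_score <- function(q, membership, labels = NULL) {
  membership <- as.integer(membership)
  if (!is.null(labels)) names(membership) <- labels
  structure(list(q = q, membership = membership),
            class = "modularity_score")
}

#' @export
print.modularity_score <- function(x, ...) {
  cat("Modularity Q =", format(x$q, digits = 6), "(",
      length(unique(x$membership)), "modules over",
      length(x$membership), "nodes )\n")
  invisible(x)
}

# symmetrized pair-contribution matrix: Q(partition) =
#   sum(diag(B)) + sum_{i<j, same module} S[i, j]
pair_matrix <- function(B) B + t(B)

#' Heuristic modularity maximization
#'
#' Alternates greedy agglomerative merging (starting from singleton
#' modules, apply the merge with the largest positive Q gain until none
#' remains) with Kernighan-Lin-style single-node moves, until a full
#' merge + refine round no longer improves Q; the best of three
#' deterministic initializations (greedy agglomeration, singletons,
#' recursive bisection) is returned.  Ties are broken by lowest
#' index, so the result is reproducible.  On graphs small enough for
#' [exhaustive_best_partition()] the heuristic almost always attains the
#' exact optimum (bounded by the test suite).
#'
#' @param A Square 0/1 adjacency matrix (dimnames, if any, become node
#'   labels of the result).
#' @param directed Use directed modularity (default).
#' @return A `modularity_score`: list with `q` and `membership`.
#' @export
maximize_modularity <- function(A, directed = TRUE) {
  A <- as.matrix(A)
  res <- .engine_max_modularity(A + 0, directed)
  new_modularity_score(res$q, res$membership, rownames(A))
}

# R reference implementation of the same heuristic (cross-checked
# against the compiled path in the tests)
maximize_modularity_ref <- function(A, directed = TRUE) {
  A <- as.matrix(A)
  B <- q_matrix(A, directed)
  S <- pair_matrix(B)
  n <- nrow(A)
  qual <- function(memb) {
    same <- outer(memb, memb, "==") & upper.tri(S)
    sum(diag(B)) + sum(S[same])
  }
  polish <- function(memb) {
    q <- qual(memb)
    repeat {
      memb <- merge_phase(S, kl_refine(S, memb))
      q2 <- qual(memb)
      if (q2 <= q + 1e-12) break
      q <- q2
    }
    list(memb = memb, q = qual(memb))
  }
  cands <- list(polish(greedy_agglomerate(S)),
                polish(seq_len(n)),
                polish(bisection_init(S)))
  best <- cands[[which.max(vapply(cands, function(c) c$q, numeric(1)))]]
  memb <- match(best$memb, unique(best$memb))
  new_modularity_score(best$q, memb, rownames(A))
}

# greedy agglomeration from singletons: repeatedly apply the merge with
# the largest positive Q gain (community-aggregated link matrix G)
greedy_agglomerate <- function(S) {
  n <- nrow(S)
  memb <- seq_len(n)
  G <- S
  diag(G) <- NA
  alive <- rep(TRUE, n)
  repeat {
    Gv <- G
    Gv[!alive, ] <- NA
    Gv[, !alive] <- NA
    best <- suppressWarnings(max(Gv, na.rm = TRUE))
    if (!is.finite(best) || best <= 1e-12) break
    idx <- which(Gv == best, arr.ind = TRUE)[1L, ]
    u <- min(idx); v <- max(idx)
    memb[memb == v] <- u
    G[u, ] <- G[u, ] + G[v, ]
    G[, u] <- G[, u] + G[, v]
    G[u, u] <- NA
    alive[v] <- FALSE
  }
  memb
}

# recursive bisection: split any community while the best two-way split
# of its members increases Q (cross-pair contributions outside the
# community are unaffected, so each split is a local 2-colouring problem)
bisection_init <- function(S) {
  n <- nrow(S)
  memb <- rep(1L, n)
  queue <- list(seq_len(n))
  next_label <- 2L
  while (length(queue)) {
    C <- queue[[1L]]
    queue <- queue[-1L]
    if (length(C) < 2L) next
    side <- best_two_colouring(S[C, C, drop = FALSE])
    if (is.null(side)) next
    gain <- -sum(S[C[side == 1L], C[side == 2L], drop = FALSE])
    # splitting removes the cross-side pair contributions
    if (gain <= 1e-12) next
    memb[C[side == 2L]] <- next_label
    next_label <- next_label + 1L
    queue <- c(queue, list(C[side == 1L]), list(C[side == 2L]))
  }
  memb
}

# 2-colouring of a community maximizing the within-side pair sum:
# exhaustive for <= 12 members, spectral + node swaps above
best_two_colouring <- function(Ssub) {
  m <- nrow(Ssub)
  if (m > 12L) {
    ev <- eigen(Ssub, symmetric = TRUE)
    side <- (ev$vectors[, 1L] >= 0) + 1L
    if (length(unique(side)) == 1L) side[which.min(ev$vectors[, 1L])] <- 1L
    return(kl_bipart_refine(Ssub, side))
  }
  ncfg <- 2L^(m - 1L)
  if (ncfg < 2L) return(NULL)
  cfg <- 1:(ncfg - 1L)
  Cm <- matrix(FALSE, ncfg - 1L, m)
  for (j in 2L:m)
    Cm[, j] <- bitwAnd(cfg, bitwShiftL(1L, j - 2L)) != 0L
  qs <- numeric(ncfg - 1L)
  for (i in seq_len(m - 1L))
    for (j in (i + 1L):m)
      if (Ssub[i, j] != 0) qs <- qs + Ssub[i, j] * (Cm[, i] == Cm[, j])
  k <- which.max(qs)
  Cm[k, ] + 1L
}

# merge whole communities while any pairwise merge gains Q
merge_phase <- function(S, memb) {
  repeat {
    memb <- match(memb, unique(memb))
    nc <- max(memb)
    if (nc == 1L) return(memb)
    Ind <- matrix(0, length(memb), nc)
    Ind[cbind(seq_along(memb), memb)] <- 1
    M <- t(Ind) %*% S %*% Ind
    diag(M) <- NA
    best <- suppressWarnings(max(M, na.rm = TRUE))
    if (!is.finite(best) || best <= 1e-12) return(memb)
    idx <- which(M == best, arr.ind = TRUE)[1L, ]
    memb[memb == max(idx)] <- min(idx)
  }
}

# single-node move refinement: move any node to the community (or a new
# singleton) that most increases Q, until a full sweep makes no move.
# SM[i, c] = total link strength from node i into community c is kept
# incrementally; column nc+1 is a standing empty community so a node can
# always split off into a singleton.
kl_refine <- function(S, memb) {
  n <- length(memb)
  memb <- match(memb, unique(memb))
  nc <- max(memb)
  Ind <- matrix(0, n, nc + 1L)
  Ind[cbind(seq_len(n), memb)] <- 1
  SM <- S %*% Ind
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      cur <- memb[i]
      li <- SM[i, ]
      li[cur] <- li[cur] - S[i, i]
      gain <- li - li[cur]
      gain[cur] <- 0
      j <- which.max(gain)
      if (gain[j] > 1e-12) {
        memb[i] <- j
        SM[, cur] <- SM[, cur] - S[, i]
        SM[, j] <- SM[, j] + S[, i]
        if (j == ncol(SM)) SM <- cbind(SM, 0)  # keep an empty slot
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

# cache of restricted-growth-string matrices (all set partitions of n)
.partition_cache <- new.env(parent = emptyenv())

rgs_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  C <- matrix(1L, 1L, 1L)
  mx <- 1L
  if (n > 1L) {
    for (k in 2L:n) {
      reps <- mx + 1L
      idx <- rep(seq_len(nrow(C)), reps)
      newlab <- unlist(lapply(seq_len(nrow(C)), function(r) seq_len(reps[r])),
                       use.names = FALSE)
      # order: for each existing partition, all label choices; but build
      # column-wise for speed
      ord <- order(idx)
      C <- cbind(C[idx, , drop = FALSE], newlab)
      mx <- pmax(mx[idx], newlab)
    }
  }
  dimnames(C) <- NULL
  .partition_cache[[key]] <- C
  C
}

#' Exact maximum-modularity partition by enumeration
#'
#' Enumerates every set partition of the nodes (Bell-number enumeration)
#' and returns the partition with maximal Q.  Intended as a test oracle;
#' limited to graphs of at most 12 nodes.
#'
#' @inheritParams maximize_modularity
#' @return A `modularity_score`.
#' @export
exhaustive_best_partition <- function(A, directed = TRUE) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n > 12L) stop("exhaustive enumeration limited to <= 12 nodes")
  B <- q_matrix(A, directed)
  S <- pair_matrix(B)
  C <- rgs_matrix(n)
  qs <- rep(sum(diag(B)), nrow(C))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (S[i, j] != 0) qs <- qs + S[i, j] * (C[, i] == C[, j])
      }
    }
  }
  best <- which.max(qs)
  new_modularity_score(qs[best], C[best, ], rownames(A))
}

#' Best split of a graph into exactly two modules
#'
#' Maximizes Q over all partitions with exactly two non-empty modules.
#' Exhaustive (all 2-colourings up to label swap) for up to 20 nodes;
#' larger graphs use spectral bisection on the symmetrized modularity
#' matrix followed by Kernighan-Lin node swaps.
#'
#' @inheritParams maximize_modularity
#' @return A `modularity_score` with membership in \{1, 2\}.
#' @export
best_bipartition <- function(A, directed = TRUE) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 nodes to bipartition")
  B <- q_matrix(A, directed)
  S <- pair_matrix(B)
  base <- sum(diag(B))
  if (n <= 20L) {
    ncfg <- 2L^(n - 1L)  # node 1 pinned to module 1
    cfg <- 1:ncfg - 1L
    Cm <- matrix(FALSE, ncfg, n)
    for (j in 2L:n) {
      Cm[, j] <- bitwAnd(cfg, bitwShiftL(1L, j - 2L)) != 0L
    }
    qs <- rep(base, ncfg)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (S[i, j] != 0) qs <- qs + S[i, j] * (Cm[, i] == Cm[, j])
      }
    }
    qs[1L] <- -Inf  # all nodes in one module: not a bipartition
    best <- which.max(qs)
    memb <- Cm[best, ] + 1L
  } else {
    ev <- eigen(S, symmetric = TRUE)
    memb <- (ev$vectors[, 1L] >= 0) + 1L
    if (length(unique(memb)) == 1L) memb[which.min(ev$vectors[, 1L])] <- 1L
    memb <- kl_bipart_refine(S, memb)
  }
  q <- base + sum(S[upper.tri(S)] * (outer(memb, memb, "==")[upper.tri(S)]))
  new_modularity_score(q, memb, rownames(A))
}

# greedy single-node side-swaps keeping both sides non-empty
kl_bipart_refine <- function(S, memb) {
  n <- length(memb)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      if (sum(memb == memb[i]) == 1L) next
      same <- setdiff(which(memb == memb[i]), i)
      other <- which(memb != memb[i])
      gain <- sum(S[i, other]) - sum(S[i, same])
      if (gain > 1e-12) {
        memb[i] <- 3L - memb[i]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

#' Modularity of a genome's displayed network
#'
#' Applies [maximize_modularity()] to the displayed (connected-node) graph
#' of a genome.
#'
#' @param genome A `network_genome` with at least one connection.
#' @param directed Use directed modularity (default).
#' @return A `modularity_score` with membership named by node labels.
#' @export
genome_modularity <- function(genome, directed = TRUE) {
  dg <- displayed_graph(genome)
  maximize_modularity(dg$A, directed)
}

# q value only, skipping label bookkeeping (hot path for MOLE / surveys)
genome_q <- function(genome, directed = TRUE) {
  ls <- genome$layers
  off <- c(0L, cumsum(ls))
  n <- sum(ls)
  A <- matrix(0, n, n)
  deg <- numeric(n)
  for (l in seq_along(genome$weights)) {
    w <- genome$weights[[l]] != 0
    A[off[l] + seq_len(ls[l]), off[l + 1L] + seq_len(ls[l + 1L])] <- w
    deg[off[l] + seq_len(ls[l])] <- deg[off[l] + seq_len(ls[l])] +
      rowSums(w)
    deg[off[l + 1L] + seq_len(ls[l + 1L])] <-
      deg[off[l + 1L] + seq_len(ls[l + 1L])] + colSums(w)
  }
  keep <- deg > 0
  if (!any(keep)) return(NA_real_)
  .engine_max_modularity(A[keep, keep, drop = FALSE], directed)$q
}

#' Does the best two-way split separate the task's subproblems?
#'
#' Checks functional modularity: whether the Q-maximizing bipartition of
#' the displayed network places all of subproblem 1's inputs in one module
#' and all of subproblem 2's inputs in the other.  Inputs without any
#' connection are not part of the displayed graph and are ignored; at
#' least one input per subproblem must be displayed.
#'
#' @param partition Named membership vector (names are node labels such as
#'   `"I1"`), e.g. `best_bipartition(displayed_graph(g)$A)$membership`.
#' @param env A `task_env` with exactly two subproblems.
#' @return Logical.
#' @export
functional_split_check <- function(partition, env) {
  if (length(env$subproblems) != 2L)
    stop("environment has no two-way subproblem decomposition")
  side <- lapply(env$subproblems, function(sp) {
    labs <- paste0("I", sp$inputs)
    partition[labs[labs %in% names(partition)]]
  })
  if (!length(side[[1L]]) || !length(side[[2L]])) return(FALSE)
  length(unique(side[[1L]])) == 1L &&
    length(unique(side[[2L]])) == 1L &&
    side[[1L]][1L] != side[[2L]][1L]
}

#' Hidden nodes that perfectly solve a subproblem
#'
#' For each subproblem of the environment, finds the displayed hidden
#' nodes whose classified output equals the subproblem answer on every
#' input pattern.  By default a node answering the exact complement on
#' every pattern also counts (a downstream weight can invert the sign);
#' `polarity = "strict"` requires the direct match.
#'
#' @param genome A `network_genome`.
#' @param env A `task_env` with subproblem metadata.
#' @param polarity `"either"` (default) or `"strict"`.
#' @param lambda,bias_sign Transfer parameters.
#' @return Named list (one element per subproblem) of node-label character
#'   vectors.
#' @export
perfect_subsolution_nodes <- function(genome, env,
                                      polarity = c("either", "strict"),
                                      lambda = 20, bias_sign = -1) {
  polarity <- match.arg(polarity)
  if (!length(env$subproblems)) stop("environment has no subproblems")
  acts <- evaluate_network(genome, env$X, lambda, bias_sign)
  nt <- node_table(genome)
  L <- length(genome$layers)
  res <- lapply(env$subproblems, function(sp) {
    hits <- character(0)
    for (l in seq(2L, L - 1L, length.out = max(0L, L - 2L))) {
      cls <- classify(acts[[l]])
      for (j in seq_len(ncol(cls))) {
        lab <- nt$label[nt$layer == l & nt$index == j]
        if (!nt$displayed[nt$layer == l & nt$index == j]) next
        agree <- cls[, j] == sp$answers
        if (all(agree) || (polarity == "either" && all(!agree)))
          hits <- c(hits, lab)
      }
    }
    hits
  })
  names(res) <- vapply(env$subproblems, function(sp) sp$name, character(1))
  res
}

#' Are there perfect sub-solution nodes for every subproblem?
#'
#' @inheritParams perfect_subsolution_nodes
#' @return Logical: `TRUE` iff each subproblem has at least one perfect
#'   sub-solution node.
#' @export
has_perfect_subsolutions <- function(genome, env,
                                     polarity = c("either", "strict"),
                                     lambda = 20, bias_sign = -1) {
  sets <- perfect_subsolution_nodes(genome, env, polarity, lambda, bias_sign)
  all(vapply(sets, length, integer(1)) > 0L)
}
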