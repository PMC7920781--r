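# Barber's quantitative bipartite modularity and its optimization.
#
# Q(partition) = (1/F) * sum over pairs (i, j) with row i and column j in
# the same module of (A_ij - k_i * d_j / F). The optimizer is a seeded
# multi-restart greedy label propagation with module merging; an exhaustive
# enumeration over all joint set-partitions serves as the oracle for small
# networks.

#' Construct a joint module partition for a bipartite network
#'
#' A partition assigns exactly one module id to every pollinator (row) and
#' every plant (column). Ids are canonicalized to contiguous integers
#' `1..n_modules` in order of first appearance over columns, then rows, so
#' equivalent labelings compare equal.
#'
#' @param row_module Integer module ids for the rows (pollinators);
#'   optionally named by species label.
#' @param col_module Integer module ids for the columns (plants).
#' @return An object of class `module_partition` with elements
#'   `row_module`, `col_module`, `n_modules`.
#' @export
module_partition <- function(row_module, col_module) {
  rm_names <- names(row_module)
  cm_names <- names(col_module)
  row_module <- as.integer(row_module)
  col_module <- as.integer(col_module)
  if (anyNA(row_module) || anyNA(col_module)) {
    abort("module ids must be non-missing integers")
  }
  if (length(row_module) == 0 || length(col_module) == 0) {
    abort("a partition needs at least one row and one column")
  }
  labs <- c(col_module, row_module)
  u <- unique(labs)
  relabeled <- match(labs, u)
  ncp <- length(col_module)
  col_module <- relabeled[seq_len(ncp)]
  row_module <- relabeled[-seq_len(ncp)]
  names(row_module) <- rm_names
  names(col_module) <- cm_names
  structure(
    list(
      row_module = row_module,
      col_module = col_module,
      n_modules = length(u)
    ),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf(
    "Module partition: %d modules over %d pollinators + %d plants\n",
    x$n_modules, length(x$row_module), length(x$col_module)
  ))
  invisible(x)
}

barber_null_deviation <- function(matrix) {
  matrix$A - outer(matrix$k, matrix$d) / matrix$total
}

#' Barber's quantitative bipartite modularity of a given partition
#'
#' Evaluates `Q = (1/F) * sum_{i,j same module} (A_ij - k_i d_j / F)`
#' exactly. The value is invariant to relabeling of module ids; the
#' single-module partition scores exactly 0.
#'
#' @param matrix An [interaction_matrix()].
#' @param partition A [module_partition()] whose dimensions match `matrix`.
#' @return The modularity `Q` (dimensionless, at most 1).
#' @export
barber_modularity <- function(matrix, partition) {
  stopifnot(inherits(matrix, "interaction_matrix"),
            inherits(partition, "module_partition"))
  if (length(partition$row_module) != nrow(matrix$A) ||
      length(partition$col_module) != ncol(matrix$A)) {
    abort("partition dimensions do not match the interaction matrix")
  }
  B <- barber_null_deviation(matrix)
  same <- outer(partition$row_module, partition$col_module, "==")
  sum(B[same]) / matrix$total
}

modularity_result <- function(partition, Q, n_restarts, seed, q_trace,
                              n_restarts_used = NA_integer_,
                              method = "label_propagation") {
  structure(
    list(
      partition = partition,
      Q = Q,
      n_modules = partition$n_modules,
      n_restarts = n_restarts,
      n_restarts_used = n_restarts_used,
      seed = seed,
      q_trace = q_trace,
      method = method
    ),
    class = "modularity_result"
  )
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf(
    "Modularity (%s): Q = %.4f, %d modules (seed %s)\n",
    x$method, x$Q, x$n_modules,
    if (is.na(x$seed)) "-" else format(x$seed)
  ))
  invisible(x)
}

# One greedy label-propagation run. Nodes start in singleton modules; in
# seeded-random order each node moves to the module with maximal strictly
# positive gain in Q (ties to the smallest module id; detaching to a fresh
# singleton is allowed). After the sweeps converge, all pairwise module
# merges with positive gain are applied greedily; sweep/merge alternation
# repeats until neither changes anything. A final pass applies zero-gain
# merges only, so equivalent-Q representations use the fewest modules.
lp_one_run <- function(B, Ftot, order, tol = 1e-12, init = NULL) {
  nr <- nrow(B)
  nc <- ncol(B)
  N <- nr + nc
  if (is.null(init)) init <- seq_len(N)   # singleton start
  rm <- init[seq_len(nr)]
  cm <- init[nr + seq_len(nc)]
  cnt <- tabulate(init, N)
  SR <- matrix(0, nr, N)          # SR[i, t]: B-weight of row i toward cols of module t
  for (j in seq_len(nc)) SR[, cm[j]] <- SR[, cm[j]] + B[, j]
  SC <- matrix(0, nc, N)          # SC[j, t]: B-weight of col j toward rows of module t
  for (i in seq_len(nr)) SC[, rm[i]] <- SC[, rm[i]] + B[i, ]
  Q <- sum(B[outer(rm, cm, "==")]) / Ftot
  q_trace <- Q

  do_merges <- function(allow_zero) {
    merged_any <- FALSE
    repeat {
      labs <- which(cnt > 0L)
      if (length(labs) < 2) break
      M <- matrix(0, N, N)
      rs <- rowsum(SR, rm)
      M[as.integer(rownames(rs)), ] <- rs
      G <- M + t(M)
      Gsub <- G[labs, labs, drop = FALSE]
      diag(Gsub) <- -Inf
      idx <- which.max(Gsub)
      g <- Gsub[idx]
      ok <- if (allow_zero) g > -tol * Ftot else g > tol * Ftot
      if (!is.finite(g) || !ok) break
      pos_r <- (idx - 1L) %% length(labs) + 1L
      pos_c <- (idx - 1L) %/% length(labs) + 1L
      a <- min(labs[pos_r], labs[pos_c])
      b <- max(labs[pos_r], labs[pos_c])
      rm[rm == b] <<- a
      cm[cm == b] <<- a
      SR[, a] <<- SR[, a] + SR[, b]; SR[, b] <<- 0
      SC[, a] <<- SC[, a] + SC[, b]; SC[, b] <<- 0
      cnt[a] <<- cnt[a] + cnt[b]; cnt[b] <<- 0L
      Q <<- Q + g / Ftot
      merged_any <- TRUE
    }
    merged_any
  }

  repeat {
    changed <- FALSE
    repeat {
      moved <- FALSE
      for (v in order) {
        if (v <= nr) {
          i <- v
          cur <- rm[i]
          s <- SR[i, ]
          cand <- which(cnt > 0L)
          if (cnt[cur] > 1L) {
            empty <- which(cnt == 0L)
            if (length(empty) > 0) cand <- c(cand, empty[1L])
          }
          gains <- s[cand] - s[cur]
          pick <- cand[which.max(gains)]
          if (s[pick] - s[cur] > tol * Ftot) {
            SC[, cur] <- SC[, cur] - B[i, ]
            SC[, pick] <- SC[, pick] + B[i, ]
            cnt[cur] <- cnt[cur] - 1L
            cnt[pick] <- cnt[pick] + 1L
            Q <- Q + (s[pick] - s[cur]) / Ftot
            rm[i] <- pick
            moved <- TRUE
          }
        } else {
          j <- v - nr
          cur <- cm[j]
          s <- SC[j, ]
          cand <- which(cnt > 0L)
          if (cnt[cur] > 1L) {
            empty <- which(cnt == 0L)
            if (length(empty) > 0) cand <- c(cand, empty[1L])
          }
          gains <- s[cand] - s[cur]
          pick <- cand[which.max(gains)]
          if (s[pick] - s[cur] > tol * Ftot) {
            SR[, cur] <- SR[, cur] - B[, j]
            SR[, pick] <- SR[, pick] + B[, j]
            cnt[cur] <- cnt[cur] - 1L
            cnt[pick] <- cnt[pick] + 1L
            Q <- Q + (s[pick] - s[cur]) / Ftot
            cm[j] <- pick
            moved <- TRUE
          }
        }
      }
      if (moved) {
        changed <- TRUE
        q_trace <- c(q_trace, Q)
      } else {
        break
      }
    }
    if (do_merges(allow_zero = FALSE)) {
      changed <- TRUE
      q_trace <- c(q_trace, Q)
    }
    if (!changed) break
  }
  do_merges(allow_zero = TRUE)
  q_trace <- c(q_trace, Q)
  list(Q = Q, rm = rm, cm = cm, q_trace = q_trace)
}

#' Search for the partition maximizing quantitative modularity
#'
#' Seeded multi-restart greedy label propagation with module merging: each
#' restart sweeps nodes in a fresh random order, moving each node to the
#' module with maximal strictly positive modularity gain, then greedily
#' merges module pairs whose union increases Q, alternating until
#' convergence; the best of `n_restarts` runs is kept. The returned Q is
#' always at least 0 (the single-module partition scores exactly 0) and the
#' whole search is deterministic given `(matrix, n_restarts, seed)`.
#'
#' @param matrix An [interaction_matrix()] with at least one row, one
#'   column, and one interaction.
#' @param n_restarts Number of independent restarts (default 50).
#' @param seed Integer seed controlling node sweep orders.
#' @return A `modularity_result`: `partition` (a [module_partition()]),
#'   `Q`, `n_modules`, `n_restarts`, `n_restarts_used` (restart attaining
#'   the best Q), `seed`, and `q_trace` (Q after each accepted improvement
#'   phase of the winning run; nondecreasing).
#' @seealso [exhaustive_best_partition()] for the small-network oracle,
#'   [barber_modularity()] for the objective.
#' @export
optimize_modules <- function(matrix, n_restarts = 50L, seed = 1L) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  if (!is.numeric(n_restarts) || length(n_restarts) != 1 ||
      is.na(n_restarts) || n_restarts < 1) {
    abort("`n_restarts` must be a single integer >= 1")
  }
  n_restarts <- as.integer(n_restarts)
  B <- barber_null_deviation(matrix)
  N <- nrow(B) + ncol(B)
  tol <- 1e-12
  best <- NULL
  best_restart <- NA_integer_
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      # first restart starts from singletons; later restarts diversify the
      # search with a uniform-random initial partition into 2..min(N, 8)
      # modules, which label propagation then refines
      init <- if (r == 1) {
        NULL
      } else {
        sample.int(sample(2:max(2, min(N, 8L)), 1), N, replace = TRUE)
      }
      run <- lp_one_run(B, matrix$total, sample.int(N), tol, init = init)
      if (is.null(best) || run$Q > best$Q + tol) {
        best <- run
        best_restart <- r
      }
    }
  })
  part <- module_partition(
    setNames(best$rm, matrix$row_labels),
    setNames(best$cm, matrix$col_labels)
  )
  # report the exactly re-evaluated objective for the returned partition
  q_exact <- barber_modularity(matrix, part)
  modularity_result(
    partition = part, Q = q_exact, n_restarts = n_restarts, seed = seed,
    q_trace = best$q_trace, n_restarts_used = best_restart
  )
}

# All restricted growth strings (canonical set-partition labelings) of
# length n, in lexicographic order; one partition per row.
restricted_growth_strings <- function(n) {
  out <- matrix(1L, 1, 1)
  maxs <- 1L
  for (k in seq_len(n)[-1]) {
    reps <- maxs + 1L
    idx <- rep.int(seq_len(nrow(out)), reps)
    lab <- unlist(lapply(maxs, function(m) seq_len(m + 1L)))
    out <- cbind(out[idx, , drop = FALSE], lab, deparse.level = 0)
    maxs <- pmax(maxs[idx], lab)
  }
  out
}

#' Exhaustive modularity optimum for small networks (test oracle)
#'
#' Enumerates every joint set-partition of the node set (columns then rows,
#' as restricted growth strings) and returns the partition with globally
#' maximal Barber modularity. Ties are broken by fewest modules, then by
#' lexicographically smallest canonical labeling. Intended as an
#' independent oracle for [optimize_modules()]; cost grows as the Bell
#' number of `rows + columns`.
#'
#' @param matrix An [interaction_matrix()].
#' @param max_total_nodes Refuse instances with more than this many nodes
#'   (default 10).
#' @return A `modularity_result` with `method = "exhaustive"`.
#' @export
exhaustive_best_partition <- function(matrix, max_total_nodes = 10L) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  nr <- nrow(matrix$A)
  nc <- ncol(matrix$A)
  N <- nr + nc
  if (N > max_total_nodes) {
    abort(sprintf(
      "instance too large for exhaustive search: %d nodes > max_total_nodes = %d",
      N, max_total_nodes
    ))
  }
  B <- barber_null_deviation(matrix)
  P <- restricted_growth_strings(N)   # node order: columns 1..nc, rows nc+1..N
  Q <- numeric(nrow(P))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      Q <- Q + B[i, j] * (P[, nc + i] == P[, j])
    }
  }
  Q <- Q / matrix$total
  qmax <- max(Q)
  cand <- which(Q > qmax - 1e-12)
  n_mod <- apply(P[cand, , drop = FALSE], 1, max)
  cand <- cand[n_mod == min(n_mod)]
  pick <- cand[1L]                    # lexicographically first canonical labeling
  part <- module_partition(
    setNames(P[pick, nc + seq_len(nr)], matrix$row_labels),
    setNames(P[pick, seq_len(nc)], matrix$col_labels)
  )
  modularity_result(
    partition = part,
    Q = barber_modularity(matrix, part),
    n_restarts = NA_integer_, seed = NA_integer_,
    q_trace = numeric(0), method = "exhaustive"
  )
}

#' Write a module partition as TSV
#'
#' Columns `node_label`, `level` (`plant` or `pollinator`) and `module_id`.
#'
#' @param result A `modularity_result` (from [optimize_modules()] or
#'   [exhaustive_best_partition()]).
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_partition <- function(result, path) {
  stopifnot(inherits(result, "modularity_result"))
  readr::write_tsv(tidy.modularity_result(result), path, progress = FALSE)
  invisible(tidy.modularity_result(result))
}
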