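# Quantitative null models preserving the grand total and connectance
# (vaznull family): cell probabilities proportional to the product of
# marginal totals, every row and column of each null occupied, the same
# number of filled cells as the observed matrix. Observed modularity is
# standardized against the null ensemble as Z_Q.

#' Draw one quantitative (vaznull-style) null matrix
#'
#' Cell probabilities are proportional to `(k_i / F) * (d_j / F)`. A
#' skeleton of filled cells with the same connectance as the input is drawn
#' first -- cells are sampled one at a time with probability proportional
#' to `p_ij` among cells whose addition still allows every row and column
#' to be covered within the remaining budget (dead ends restart the draw,
#' capped at 1,000 attempts) -- and the remaining `F - fill` interactions
#' are then distributed multinomially over the skeleton cells with
#' probability proportional to `p_ij`. The draw consumes the current RNG
#' stream; seed it with [withr::with_seed()] or `set.seed()` for
#' reproducibility.
#'
#' @param matrix An [interaction_matrix()]; its fill count must be at least
#'   `max(rows, cols)`, otherwise no skeleton can cover every row and
#'   column.
#' @return An [interaction_matrix()] with the same dimensions, labels,
#'   grand total and fill count, and all row/column totals at least 1.
#' @export
vaznull_sample <- function(matrix) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  A <- matrix$A
  nr <- nrow(A)
  nc <- ncol(A)
  fill <- matrix$fill
  if (fill < max(nr, nc)) {
    abort(sprintf(
      "unsatisfiable skeleton: fill count %d < max(rows, cols) = %d, so not every row and column can be occupied",
      fill, max(nr, nc)
    ))
  }
  p <- outer(matrix$k, matrix$d)
  p <- p / sum(p)
  skeleton <- NULL
  for (attempt in seq_len(1000L)) {
    skeleton <- draw_skeleton(p, fill, nr, nc)
    if (!is.null(skeleton)) break
  }
  if (is.null(skeleton)) {
    abort("skeleton draw failed 1,000 times: row/column coverage unsatisfiable")
  }
  extra <- matrix$total - fill
  pr <- p[skeleton]
  counts <- rep(1L, fill)
  if (extra > 0) {
    counts <- counts + as.integer(rmultinom(1, extra, pr / sum(pr)))
  }
  out <- base::matrix(0L, nr, nc, dimnames = dimnames(A))
  out[skeleton] <- counts
  interaction_matrix(out)
}

# Sequential skeleton draw; returns cell indices or NULL on a dead end.
draw_skeleton <- function(p, fill, nr, nc) {
  n_cells <- nr * nc
  chosen <- logical(n_cells)
  row_cov <- logical(nr)
  col_cov <- logical(nc)
  row_of <- rep.int(seq_len(nr), nc)
  col_of <- rep.int(seq_len(nc), rep.int(nr, nc))
  picked <- integer(fill)
  n_sel <- 0L
  while (n_sel < fill) {
    unc_r <- sum(!row_cov)
    unc_c <- sum(!col_cov)
    remaining <- fill - n_sel
    if (unc_r == 0L && unc_c == 0L) {
      # coverage done: the rest is weighted sampling without replacement
      left <- which(!chosen)
      picked[(n_sel + 1L):fill] <-
        left[sample.int(length(left), remaining, prob = p[left])]
      n_sel <- fill
      break
    }
    new_unc_r <- unc_r - !row_cov[row_of]
    new_unc_c <- unc_c - !col_cov[col_of]
    feasible <- !chosen & (pmax(new_unc_r, new_unc_c) <= remaining - 1L)
    idx <- which(feasible)
    if (length(idx) == 0L) return(NULL)
    cell <- idx[sample.int(length(idx), 1L, prob = p[idx])]
    chosen[cell] <- TRUE
    row_cov[row_of[cell]] <- TRUE
    col_cov[col_of[cell]] <- TRUE
    n_sel <- n_sel + 1L
    picked[n_sel] <- cell
  }
  sort(picked)
}

#' Generate a null ensemble with modularity and pooled c/z values
#'
#' Draws `n` vaznull matrices; for each draw the modularity optimizer is
#' run with the same restart budget as the observed network and the null's
#' own best partition is used to compute lower-level (plant) weighted c and
#' z values, which are pooled across all nulls into single vectors. Fully
#' reproducible from the seed.
#'
#' @param matrix The observed [interaction_matrix()].
#' @param n Number of null matrices (default 100; at least 2 so the null
#'   standard deviation is defined).
#' @param seed Integer seed for the whole ensemble.
#' @param n_restarts Optimizer restarts per null matrix (default 50,
#'   matching the observed-network default).
#' @param level Trophic level whose c/z values are pooled (default
#'   `"plant"`).
#' @return A `null_ensemble` object: `n`, `q_null` (vector of null Q
#'   values), `pooled_c`, `pooled_z`, `seed`, `n_restarts`, `level`.
#' @export
null_ensemble <- function(matrix, n = 100L, seed = 1L, n_restarts = 50L,
                          level = c("plant", "pollinator")) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  level <- match.arg(level)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 2) {
    abort("`n` must be a single integer >= 2 (the null sd is undefined otherwise)")
  }
  n <- as.integer(n)
  q_null <- numeric(n)
  pooled_c <- vector("list", n)
  pooled_z <- vector("list", n)
  withr::with_seed(seed, {
    child_seeds <- sample.int(2147483646L, n)
    for (b in seq_len(n)) {
      null_mat <- vaznull_sample(matrix)
      opt <- optimize_modules(null_mat, n_restarts = n_restarts,
                              seed = child_seeds[b])
      q_null[b] <- opt$Q
      sc <- role_scores(null_mat, opt$partition, level = level)
      pooled_c[[b]] <- sc$c
      pooled_z[[b]] <- sc$z
    }
  })
  structure(
    list(
      n = n,
      q_null = q_null,
      pooled_c = unlist(pooled_c),
      pooled_z = unlist(pooled_z),
      seed = seed,
      n_restarts = as.integer(n_restarts),
      level = level
    ),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "Null ensemble: %d vaznull draws (seed %d), Q_null = %.4f +/- %.4f\n",
    x$n, x$seed, mean(x$q_null), sd(x$q_null)
  ))
  invisible(x)
}

#' Standardize observed modularity against a null ensemble (Z_Q)
#'
#' `Z_Q = (Q_observed - mean(Q_null)) / sd(Q_null)` with the sample (n-1)
#' standard deviation; `Z_Q > 2` (strictly) flags significantly modular
#' structure. `Q_adjusted = Q_observed - mean(Q_null)`. When the null sd is
#' zero, `Z_Q` is `+Inf` (significant) if the observed Q exceeds the null
#' mean, and an error otherwise.
#'
#' @param Q_observed Observed modularity (a number, or a
#'   `modularity_result`).
#' @param ensemble A [null_ensemble()].
#' @param z_sig Significance cutoff on Z_Q (default 2).
#' @return A `zq_result` object with `Q_observed`, `Q_null_mean`,
#'   `Q_null_sd`, `Z_Q`, `Q_adjusted`, `significant`, `n_nulls`.
#' @export
modularity_z_score <- function(Q_observed, ensemble, z_sig = 2) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (inherits(Q_observed, "modularity_result")) {
    Q_observed <- Q_observed$Q
  }
  if (ensemble$n < 2) abort("ensemble must contain at least 2 nulls")
  mu <- mean(ensemble$q_null)
  sdev <- sd(ensemble$q_null)
  if (sdev == 0) {
    if (Q_observed > mu) {
      z <- Inf
    } else {
      abort("null sd is zero and Q_observed does not exceed the null mean: Z_Q undefined")
    }
  } else {
    z <- (Q_observed - mu) / sdev
  }
  structure(
    list(
      Q_observed = Q_observed,
      Q_null_mean = mu,
      Q_null_sd = sdev,
      Z_Q = z,
      Q_adjusted = Q_observed - mu,
      significant = z > z_sig,
      z_sig = z_sig,
      n_nulls = ensemble$n
    ),
    class = "zq_result"
  )
}

#' @export
print.zq_result <- function(x, ...) {
  cat(sprintf(
    "Q = %.4f vs %d nulls (%.4f +/- %.4f): Z_Q = %.2f, Q_adjusted = %.4f%s\n",
    x$Q_observed, x$n_nulls, x$Q_null_mean, x$Q_null_sd, x$Z_Q,
    x$Q_adjusted,
    if (x$significant) " (significantly modular)" else ""
  ))
  invisible(x)
}

#' Write an ensemble/Z_Q summary as JSON (and optionally the null Q values)
#'
#' @param zq A `zq_result` from [modularity_z_score()].
#' @param ensemble The [null_ensemble()] it was computed from.
#' @param path Output JSON path.
#' @param q_null_path Optional TSV path for the individual null Q values.
#' @return The summary list, invisibly.
#' @export
write_ensemble_summary <- function(zq, ensemble, path, q_null_path = NULL) {
  stopifnot(inherits(zq, "zq_result"), inherits(ensemble, "null_ensemble"))
  out <- list(
    n = ensemble$n,
    seed = ensemble$seed,
    Q_observed = zq$Q_observed,
    Q_null_mean = zq$Q_null_mean,
    Q_null_sd = zq$Q_null_sd,
    Z_Q = zq$Z_Q,
    Q_adjusted = zq$Q_adjusted,
    significant = zq$significant
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(q_null_path)) {
    readr::write_tsv(
      tibble::tibble(draw = seq_len(ensemble$n), Q = ensemble$q_null),
      q_null_path, progress = FALSE
    )
  }
  invisible(out)
}
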