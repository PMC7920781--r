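# broom-style tidy()/glance() methods for the fitted objects.

#' Tidy methods for pollinet objects
#'
#' `tidy()` returns one row per elementary unit: network edges for an
#' interaction matrix, node-module assignments for a modularity result,
#' per-draw null modularity for an ensemble, and the report rows of a
#' pipeline result.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_pollinet
NULL

#' Glance methods for pollinet objects
#'
#' `glance()` returns a one-row summary tibble.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance_pollinet
NULL

#' @rdname tidy_pollinet
#' @export
tidy.modularity_result <- function(x, ...) {
  tibble::tibble(
    node_label = c(names(x$partition$col_module),
                   names(x$partition$row_module)),
    level = c(rep("plant", length(x$partition$col_module)),
              rep("pollinator", length(x$partition$row_module))),
    module_id = c(unname(x$partition$col_module),
                  unname(x$partition$row_module))
  )
}

#' @rdname glance_pollinet
#' @export
glance.modularity_result <- function(x, ...) {
  tibble::tibble(
    Q = x$Q,
    n_modules = x$n_modules,
    n_restarts = x$n_restarts,
    n_restarts_used = x$n_restarts_used,
    seed = x$seed,
    method = x$method
  )
}

#' @rdname tidy_pollinet
#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble::tibble(draw = seq_len(x$n), Q = x$q_null)
}

#' @rdname glance_pollinet
#' @export
glance.null_ensemble <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    Q_null_mean = mean(x$q_null),
    Q_null_sd = sd(x$q_null),
    seed = x$seed,
    level = x$level
  )
}

#' @rdname glance_pollinet
#' @export
glance.zq_result <- function(x, ...) {
  tibble::tibble(
    Q_observed = x$Q_observed,
    Q_null_mean = x$Q_null_mean,
    Q_null_sd = x$Q_null_sd,
    Z_Q = x$Z_Q,
    Q_adjusted = x$Q_adjusted,
    significant = x$significant,
    n_nulls = x$n_nulls
  )
}

#' @rdname glance_pollinet
#' @export
glance.chao_estimate <- function(x, ...) {
  tibble::tibble(
    S_obs = x$S_obs,
    S_est = x$S_est,
    se = x$se,
    f1 = x$f1,
    f2 = x$f2,
    pct_detected = x$pct_detected
  )
}

#' @rdname tidy_pollinet
#' @export
tidy.abundance_vector <- function(x, ...) {
  tibble::tibble(label = x$labels, count = x$counts)
}

#' @rdname tidy_pollinet
#' @export
tidy.pipeline_result <- function(x, ...) {
  x$report
}

#' @rdname glance_pollinet
#' @export
glance.completeness_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$species$chao), entity = "species",
                  .before = 1),
    dplyr::mutate(glance(x$interactions$chao), entity = "interactions",
                  .before = 1)
  )
}
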