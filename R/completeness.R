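# Sampling-completeness assessment: Chao1 asymptotic richness and
# individual-based rarefaction, for pollinator species and for unique
# plant-pollinator interactions (each non-zero cell is one interaction
# type with abundance equal to its count).

#' Construct an abundance vector
#'
#' A labelled vector of positive integer abundances: either species
#' (individuals per species) or interaction types (visits per non-zero
#' plant--pollinator pair).
#'
#' @param labels Entity labels.
#' @param counts Positive integer abundances, one per label.
#' @return An object of class `abundance_vector` with `labels`, `counts`,
#'   `N` (total individuals) and `S_obs` (number of entities).
#' @export
abundance_vector <- function(labels, counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) abort("abundance vector is empty")
  if (anyNA(counts) || any(counts < 1) || any(counts != round(counts))) {
    abort("abundances must be positive integers")
  }
  if (length(labels) != length(counts)) {
    abort("labels and counts differ in length")
  }
  structure(
    list(
      labels = as.character(labels),
      counts = as.integer(counts),
      N = as.integer(sum(counts)),
      S_obs = length(counts)
    ),
    class = "abundance_vector"
  )
}

#' Interaction-type abundances from an interaction matrix
#'
#' One entity per non-zero cell: the unique plant--pollinator interaction,
#' with abundance equal to the cell's visit count. The total equals the
#' matrix grand total and the number of entities equals the fill count.
#'
#' @param matrix An [interaction_matrix()].
#' @return An [abundance_vector()].
#' @export
interaction_abundances <- function(matrix) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  idx <- which(matrix$A > 0, arr.ind = TRUE)
  abundance_vector(
    paste(matrix$row_labels[idx[, 1]], matrix$col_labels[idx[, 2]],
          sep = " -- "),
    matrix$A[idx]
  )
}

#' Species abundances from an interaction matrix
#'
#' Per-species individual counts: the marginal visit totals of one trophic
#' level (for pollinators, the number of captured individuals per species).
#'
#' @param matrix An [interaction_matrix()].
#' @param level `"pollinator"` (default) or `"plant"`.
#' @return An [abundance_vector()].
#' @export
species_abundances <- function(matrix, level = c("pollinator", "plant")) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  level <- match.arg(level)
  counts <- if (level == "pollinator") matrix$k else matrix$d
  abundance_vector(names(counts), counts)
}

#' Chao1 asymptotic richness
#'
#' Classic (bias-uncorrected) Chao1: `S_est = S_obs + f1^2 / (2 f2)` with
#' singleton count `f1` and doubleton count `f2`; when `f2 = 0` the
#' fallback `S_est = S_obs + f1 (f1 - 1) / 2` is used. The standard error
#' comes from Chao's abundance-based variance (for `f2 > 0`:
#' `var = f2 * (r^4/4 + r^3 + r^2/2)` with `r = f1/f2`). `S_est >= S_obs`
#' always, with equality iff `f1 <= 1`.
#'
#' @param abund An [abundance_vector()].
#' @return An object of class `chao_estimate` with `S_obs`, `S_est`, `se`,
#'   `f1`, `f2` and `pct_detected` (`100 * S_obs / S_est`).
#' @export
chao1 <- function(abund) {
  stopifnot(inherits(abund, "abundance_vector"))
  counts <- abund$counts
  S_obs <- abund$S_obs
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  if (f2 > 0) {
    S_est <- S_obs + f1^2 / (2 * f2)
    r <- f1 / f2
    v <- f2 * (r^4 / 4 + r^3 + r^2 / 2)
  } else {
    S_est <- S_obs + f1 * (f1 - 1) / 2
    v <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 -
      if (S_est > 0) f1^4 / (4 * S_est) else 0
  }
  structure(
    list(
      S_obs = S_obs,
      S_est = S_est,
      se = sqrt(max(v, 0)),
      f1 = f1,
      f2 = f2,
      pct_detected = 100 * S_obs / S_est
    ),
    class = "chao_estimate"
  )
}

#' @export
print.chao_estimate <- function(x, ...) {
  cat(sprintf(
    "Chao1: S_obs = %d, S_est = %.1f +/- %.1f (f1 = %d, f2 = %d); %d%% detected\n",
    x$S_obs, x$S_est, x$se, x$f1, x$f2, round(x$pct_detected)
  ))
  invisible(x)
}

#' Percentage of the estimated richness detected
#'
#' @param est A [chao1()] estimate.
#' @return `100 * S_obs / S_est` (exact; round for reporting).
#' @export
percent_detected <- function(est) {
  stopifnot(inherits(est, "chao_estimate"))
  if (est$S_est <= 0) abort("S_est must be positive")
  100 * est$S_obs / est$S_est
}

#' Individual-based rarefaction curve
#'
#' Expected richness in a random subsample of n individuals drawn without
#' replacement: `E[S(n)] = S_obs - sum_i C(N - N_i, n) / C(N, n)`
#' (hypergeometric expectation). Binomial coefficients are evaluated in
#' log space so totals in the thousands do not overflow. The curve is
#' monotone nondecreasing with `E[S(N)] = S_obs` exactly.
#'
#' @param abund An [abundance_vector()].
#' @param grid Integer subsample sizes in `[1, N]`; defaults to about 25
#'   evenly spaced sizes ending at `N`.
#' @return A tibble of class `rarefaction_curve` with columns `n` and
#'   `expected_richness`.
#' @export
rarefaction_curve <- function(abund, grid = NULL) {
  stopifnot(inherits(abund, "abundance_vector"))
  N <- abund$N
  if (is.null(grid)) {
    grid <- unique(c(1L, as.integer(round(seq(1, N, length.out = 25)))))
  }
  grid <- as.integer(grid)
  if (anyNA(grid) || any(grid < 1) || any(grid > N)) {
    abort(sprintf("subsample sizes must lie in [1, %d]", N))
  }
  expected <- vapply(grid, function(n) {
    abund$S_obs - sum(exp(lchoose(N - abund$counts, n) - lchoose(N, n)))
  }, numeric(1))
  out <- tibble::tibble(n = grid, expected_richness = expected)
  class(out) <- c("rarefaction_curve", class(out))
  out
}

#' Full sampling-completeness report for a network
#'
#' Chao1 estimates and rarefaction curves for the pollinator species
#' assemblage and for the unique plant--pollinator interactions of one
#' interaction matrix.
#'
#' @param matrix An [interaction_matrix()].
#' @return A list of class `completeness_report` with elements `species`
#'   and `interactions`, each holding a `chao` estimate and a `curve`.
#' @export
completeness_report <- function(matrix) {
  sp <- species_abundances(matrix, "pollinator")
  ia <- interaction_abundances(matrix)
  structure(
    list(
      species = list(chao = chao1(sp), curve = rarefaction_curve(sp)),
      interactions = list(chao = chao1(ia), curve = rarefaction_curve(ia))
    ),
    class = "completeness_report"
  )
}

#' @export
print.completeness_report <- function(x, ...) {
  cat("Pollinator species  : ")
  print(x$species$chao)
  cat("Unique interactions : ")
  print(x$interactions$chao)
  invisible(x)
}

#' Write a completeness report (JSON summary plus curve TSVs)
#'
#' @param report A [completeness_report()].
#' @param path Output JSON path; curves are written next to it as
#'   `<path-sans-ext>_species_curve.tsv` and
#'   `<path-sans-ext>_interactions_curve.tsv`.
#' @return The summary list, invisibly.
#' @export
write_completeness <- function(report, path) {
  stopifnot(inherits(report, "completeness_report"))
  summ <- lapply(report, function(part) {
    est <- part$chao
    list(
      S_obs = est$S_obs, S_est = est$S_est, se = est$se,
      f1 = est$f1, f2 = est$f2,
      pct_detected = round(est$pct_detected)
    )
  })
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA)
  stem <- sub("\\.[[:alnum:]]+$", "", path)
  readr::write_tsv(tibble::as_tibble(report$species$curve),
                   paste0(stem, "_species_curve.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(report$interactions$curve),
                   paste0(stem, "_interactions_curve.tsv"), progress = FALSE)
  invisible(summ)
}
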