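# Weighted bipartite interaction matrix: rows = pollinators (higher trophic
# level), columns = plants (lower trophic level), cells = visit counts.

#' Construct an interaction matrix object
#'
#' Wraps a non-negative integer matrix (rows = pollinators, columns =
#' plants) together with its marginals. All-zero rows and columns are
#' dropped: a species with no observed interactions is not part of the
#' network. Cell values are interaction frequencies; zeros mean no
#' interaction.
#'
#' @param A A non-negative numeric matrix with integer cell values. Row and
#'   column names are used as species labels; defaults are generated when
#'   absent.
#' @return An object of class `interaction_matrix`: a list with elements
#'   `A` (the matrix), `row_labels`, `col_labels`, `k` (per-pollinator visit
#'   totals), `d` (per-plant visit totals), `total` (grand total F) and
#'   `fill` (number of non-zero cells).
#' @export
interaction_matrix <- function(A) {
  A <- as.matrix(A)
  if (!is.numeric(A)) abort("interaction matrix must be numeric")
  if (anyNA(A) || any(A < 0) || any(A != round(A))) {
    abort("interaction matrix cells must be non-negative integers")
  }
  storage.mode(A) <- "integer"
  if (is.null(rownames(A))) {
    rownames(A) <- sprintf("pollinator_%03d", seq_len(nrow(A)))
  }
  if (is.null(colnames(A))) {
    colnames(A) <- sprintf("plant_%02d", seq_len(ncol(A)))
  }
  A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
  if (nrow(A) == 0 || ncol(A) == 0 || sum(A) == 0) {
    abort("no interactions to build an interaction matrix from")
  }
  structure(
    list(
      A = A,
      row_labels = rownames(A),
      col_labels = colnames(A),
      k = rowSums(A),
      d = colSums(A),
      total = sum(A),
      fill = sum(A > 0)
    ),
    class = "interaction_matrix"
  )
}

#' Build a weighted interaction matrix from visitation records
#'
#' Aggregates visit counts over all rows sharing a (pollinator, plant) pair:
#' `A[pollinator, plant]` is the total number of recorded visits. The grand
#' total equals the sum of the `count` column, and species with zero total
#' are absent by construction.
#'
#' @param records A record table (see [as_records()]); must be non-empty.
#' @return An [interaction_matrix()] object.
#' @examples
#' recs <- tibble::tibble(
#'   plant = c("P1", "P1", "P2"), pollinator = c("B1", "B2", "B2"),
#'   guild = "bee", location = "loc_1", year = 2017, season = "rainy",
#'   sample_id = "s1", count = c(2, 1, 3)
#' )
#' build_matrix(recs)
#' @export
build_matrix <- function(records) {
  records <- as_records(records)
  if (nrow(records) == 0) {
    abort("no interactions to build an interaction matrix from")
  }
  agg <- records |>
    dplyr::count(.data$pollinator, .data$plant,
                 wt = .data$count, name = "weight")
  pols <- sort(unique(agg$pollinator))
  plants <- sort(unique(agg$plant))
  A <- matrix(0L, length(pols), length(plants),
              dimnames = list(pols, plants))
  A[cbind(match(agg$pollinator, pols), match(agg$plant, plants))] <-
    as.integer(agg$weight)
  interaction_matrix(A)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "Interaction matrix: %d pollinators x %d plants, %d visits, %d links (connectance %.3f)\n",
    nrow(x$A), ncol(x$A), x$total, x$fill,
    x$fill / (nrow(x$A) * ncol(x$A))
  ))
  invisible(x)
}

#' @rdname tidy_pollinet
#' @export
tidy.interaction_matrix <- function(x, ...) {
  idx <- which(x$A > 0, arr.ind = TRUE)
  tibble::tibble(
    pollinator = x$row_labels[idx[, 1]],
    plant = x$col_labels[idx[, 2]],
    weight = as.integer(x$A[idx])
  ) |>
    dplyr::arrange(.data$pollinator, .data$plant)
}

#' @rdname glance_pollinet
#' @export
glance.interaction_matrix <- function(x, ...) {
  tibble::tibble(
    pollinators = nrow(x$A),
    plants = ncol(x$A),
    visits = x$total,
    links = x$fill,
    connectance = x$fill / (nrow(x$A) * ncol(x$A))
  )
}

#' Write / read an interaction matrix as TSV
#'
#' The matrix is stored with plant labels as the first row (header) and
#' pollinator labels in the first column; cells are integer counts. The
#' round trip `write_matrix()` then `read_matrix()` reproduces the matrix,
#' labels and total exactly.
#'
#' @param matrix An [interaction_matrix()].
#' @param path Output (or input) TSV path.
#' @return `write_matrix()` returns `matrix` invisibly; `read_matrix()`
#'   returns an [interaction_matrix()].
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  df <- tibble::as_tibble(as.data.frame(matrix$A, check.names = FALSE))
  df <- dplyr::bind_cols(tibble::tibble(pollinator = matrix$row_labels), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(matrix)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    pollinator = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df$pollinator
  interaction_matrix(A)
}

#' Write an interaction matrix as an edge list
#'
#' One row per non-zero cell with columns `pollinator, plant, weight`.
#'
#' @inheritParams write_matrix
#' @return The edge-list tibble, invisibly.
#' @export
write_edge_list <- function(matrix, path) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  edges <- tidy.interaction_matrix(matrix)
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(edges)
}
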