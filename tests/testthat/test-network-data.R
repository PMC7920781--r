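test_that("read_records parses a valid file and preserves totals and order", {
  path <- write_records_csv(toy_records())
  recs <- read_records(path)
  expect_equal(nrow(recs), 5)
  expect_equal(sum(recs$count), 8)
  expect_equal(recs$plant, toy_records()$plant)
  expect_true(is.integer(recs$count))
})

test_that("read_records rejects malformed input with informative errors", {
  broken <- toy_records()[, setdiff(names(toy_records()), "pollinator")]
  expect_error(read_records(write_records_csv(broken)), "pollinator")

  neg <- toy_records()
  neg$count[3] <- -1L
  expect_error(read_records(write_records_csv(neg)), "row\\(s\\): 3")

  txt <- toy_records()
  txt$count <- as.character(txt$count)
  txt$count[2] <- "many"
  expect_error(read_records(write_records_csv(txt)), "positive integer")

  expect_error(read_records(tempfile()), "not found")
})

test_that("an empty file with a valid header yields an empty record table", {
  empty <- toy_records()[0, ]
  recs <- read_records(write_records_csv(empty))
  expect_equal(nrow(recs), 0)
})

test_that("as_records trims whitespace so label matching is exact", {
  recs <- toy_records()
  recs$plant[1] <- "  P1 "
  out <- as_records(recs)
  expect_equal(out$plant[1], "P1")
})

test_that("build_matrix aggregates counts and conserves the grand total", {
  recs <- tibble::tibble(
    plant = c("P1", "P1", "P2"),
    pollinator = c("B1", "B2", "B2"),
    guild = "bee", location = "l", year = 2017L, season = "rainy",
    sample_id = "s", count = c(2L, 1L, 3L)
  )
  m <- build_matrix(recs)
  expect_equal(unname(m$A[cbind(c("B1", "B2", "B2"), c("P1", "P1", "P2"))]),
               c(2L, 1L, 3L))
  expect_equal(m$total, 6L)
  expect_equal(sum(m$A == 0), 1)
  expect_equal(sum(m$k), m$total)
  expect_equal(sum(m$d), m$total)

  single <- build_matrix(dplyr::mutate(recs[1, ], count = 5L))
  expect_equal(dim(single$A), c(1L, 1L))
  expect_equal(unname(single$A[1, 1]), 5L)

  expect_error(build_matrix(toy_records()[0, ]), "no interactions")
})

test_that("build_matrix drops species with zero totals and forbids zero margins", {
  m <- build_matrix(toy_records())
  expect_true(all(m$k >= 1))
  expect_true(all(m$d >= 1))
  expect_equal(m$total, sum(toy_records()$count))
})

test_that("subset_records implements exact filter semantics", {
  recs <- toy_records()
  expect_identical(subset_records(recs), as_records(recs))
  y18 <- subset_records(recs, year = 2018)
  expect_true(all(y18$year == 2018))
  expect_equal(nrow(y18), 2)
  both <- subset_records(recs, location = "loc2", season = "dry")
  expect_equal(nrow(both), 1)
  expect_warning(subset_records(recs, location = "nowhere"), "matched no rows")
})

test_that("subset_records is idempotent and commutes across filter dimensions", {
  recs <- toy_records()
  once <- subset_records(recs, year = 2017, season = "rainy")
  expect_identical(subset_records(once, year = 2017, season = "rainy"), once)
  a <- subset_records(subset_records(recs, year = 2017), season = "rainy")
  b <- subset_records(subset_records(recs, season = "rainy"), year = 2017)
  expect_identical(a, b)
})

test_that("reduce_by_occurrence applies the single-pass location filter", {
  # plant A at loc1 only; plant B at loc1 & loc2; bee X at both locations
  recs <- tibble::tibble(
    plant = c("A", "B", "B"),
    pollinator = c("X", "X", "X"),
    guild = "bee", location = c("loc1", "loc1", "loc2"),
    year = 2017L, season = "rainy", sample_id = c("s1", "s2", "s3"),
    count = 1L
  )
  red <- reduce_by_occurrence(recs, min_locations = 2)
  expect_setequal(unique(red$plant), "B")
  expect_setequal(unique(red$pollinator), "X")
  expect_equal(nrow(red), 2)

  expect_identical(reduce_by_occurrence(recs, min_locations = 1),
                   as_records(recs))
  expect_error(reduce_by_occurrence(recs, min_locations = 0), "min_locations")
})

test_that("occurrence filtering is computed on the input, not iterated", {
  # bee Y occurs at 2 locations only via plant A's rows; removing A must
  # not retroactively exclude Y
  recs <- tibble::tibble(
    plant = c("A", "A", "B", "B"),
    pollinator = c("Y", "Y", "Y", "Z"),
    guild = "bee",
    location = c("loc1", "loc2", "loc1", "loc1"),
    year = 2017L, season = "rainy",
    sample_id = c("s1", "s2", "s3", "s4"),
    count = 1L
  )
  red <- reduce_by_occurrence(recs, min_locations = 2)
  # A kept (2 locations); B dropped (1 location); Y kept from input occurrence
  expect_setequal(unique(red$plant), "A")
  expect_setequal(unique(red$pollinator), "Y")
})

test_that("reduce_by_occurrence output is a row-subset of its input", {
  recs <- as_records(toy_records())
  red <- reduce_by_occurrence(recs, min_locations = 2)
  key <- function(x) paste(x$plant, x$pollinator, x$sample_id)
  expect_true(all(key(red) %in% key(recs)))
})

test_that("matrix TSV round trip reproduces cells, labels and total exactly", {
  m <- build_matrix(toy_records())
  path <- tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_identical(back$A, m$A)
  expect_identical(back$total, m$total)
  expect_identical(back$row_labels, m$row_labels)
  expect_identical(back$col_labels, m$col_labels)
})

test_that("edge list export matches the matrix tidy form", {
  m <- build_matrix(toy_records())
  path <- tempfile(fileext = ".tsv")
  edges <- write_edge_list(m, path)
  expect_equal(sum(edges$weight), m$total)
  expect_equal(nrow(edges), m$fill)
  reread <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(reread), m$fill)
})
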