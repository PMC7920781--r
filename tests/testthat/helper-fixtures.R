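# Fixtures built in code: a small visitation table and canonical block
# matrices used across the suite.

toy_records <- function() {
  tibble::tibble(
    plant = c("P1", "P1", "P2", "P2", "P3"),
    pollinator = c("B1", "B2", "B2", "B3", "B1"),
    guild = c("bee", "bee", "bee", "butterfly", "bee"),
    location = c("loc1", "loc1", "loc2", "loc2", "loc1"),
    year = c(2017L, 2017L, 2018L, 2018L, 2017L),
    season = c("rainy", "rainy", "rainy", "dry", "rainy"),
    sample_id = c("s1", "s1", "s2", "s3", "s4"),
    floral_abundance = c(10, 10, 25, NA, 5),
    count = c(1L, 1L, 2L, 1L, 3L)
  )
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  readr::write_csv(records, path, progress = FALSE)
  path
}

# k equal-sized all-ones blocks of size block x block
block_matrix <- function(k, block = 2L, weight = 1L) {
  n <- k * block
  A <- matrix(0L, n, n)
  for (b in seq_len(k) - 1L) {
    A[b * block + seq_len(block), b * block + seq_len(block)] <- weight
  }
  interaction_matrix(A)
}

perfect_partition <- function(k, block = 2L) {
  module_partition(rep(seq_len(k), each = block), rep(seq_len(k), each = block))
}

random_small_matrix <- function(max_dim = 4L, max_cell = 5L) {
  repeat {
    nr <- sample.int(max_dim, 1)
    nc <- sample.int(max_dim, 1)
    A <- matrix(sample(0:max_cell, nr * nc, replace = TRUE), nr, nc)
    if (sum(A) > 0) {
      m <- tryCatch(interaction_matrix(A), error = function(e) NULL)
      if (!is.null(m)) return(m)
    }
  }
}

# restrict a planted true partition to the species actually observed
truth_for_matrix <- function(community, mat) {
  module_partition(
    setNames(
      community$true_partition$row_module[
        match(mat$row_labels, community$pollinators)
      ],
      mat$row_labels
    ),
    setNames(
      community$true_partition$col_module[
        match(mat$col_labels, community$plants)
      ],
      mat$col_labels
    )
  )
}

# one-site, one-session, deep-sampling design for recovery experiments
deep_design <- function(samples = 20L) {
  sampling_design(
    locations = "loc_1", years = 2018L, seasons = "rainy",
    samples_per_plant_per_location = samples,
    detection = c(bee = 1, butterfly = 1),
    plant_locations = "all"
  )
}
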