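test_that("community generation is reproducible and shapes blocks evenly", {
  a <- generate_community(6, 6, 3, lambda_in = 2, lambda_out = 0,
                          seed = 81)
  b <- generate_community(6, 6, 3, lambda_in = 2, lambda_out = 0,
                          seed = 81)
  expect_identical(a$rate_matrix, b$rate_matrix)
  expect_identical(a$guild, b$guild)
  expect_identical(a$true_partition, b$true_partition)

  # lambda_out = 0 forces an exact 3-block rate matrix
  same <- outer(a$true_partition$row_module, a$true_partition$col_module,
                "==")
  expect_true(all(a$rate_matrix[same] == 2))
  expect_true(all(a$rate_matrix[!same] == 0))
  expect_equal(unname(table(a$true_partition$col_module)),
               rep(2L, 3), ignore_attr = TRUE)

  c2 <- generate_community(6, 6, 3, seed = 82)
  expect_false(identical(a$guild, c2$guild))
  expect_error(generate_community(3, 3, 5), "n_modules")
  expect_error(generate_community(4, 4, 2, lambda_in = 1, lambda_out = 2),
               "lambda")
})

test_that("sampling an all-zero-rate community yields an empty table", {
  comm <- generate_community(3, 4, 2, lambda_in = 1e-12, lambda_out = 0,
                             seed = 83)
  comm$rate_matrix[] <- 0
  recs <- sample_visits(comm, deep_design(2), seed = 84)
  expect_equal(nrow(recs), 0)
  expect_true(all(c("plant", "pollinator", "count") %in% names(recs)))
})

test_that("observed visit totals concentrate on the design expectation", {
  comm <- generate_community(4, 8, 2, lambda_in = 1, lambda_out = 0.2,
                             seed = 85, n_continuous = 4,
                             abundance_effect = 0)
  des <- deep_design(10)
  # all plants continuous and present at the single site: expectation is
  # sum of all rates x samples
  expected <- sum(comm$rate_matrix) * 10
  totals <- vapply(1:20, function(s) {
    sum(sample_visits(comm, des, seed = s)$count)
  }, numeric(1))
  # Poisson sums: sd = sqrt(expected); the 20-seed mean has sd/sqrt(20)
  expect_lt(abs(mean(totals) - expected), 3 * sqrt(expected / 20))
})

test_that("brief-phenology plants are absent outside the rainy season", {
  comm <- generate_community(6, 8, 2, lambda_in = 1.5, lambda_out = 0.1,
                             seed = 86, n_continuous = 2)
  brief <- names(comm$phenology)[comm$phenology == "brief"]
  dry_only <- sampling_design(
    locations = "loc_1", years = 2018L, seasons = "dry",
    sessions = tibble::tibble(year = 2018L, season = "dry"),
    samples_per_plant_per_location = 5L,
    detection = c(bee = 1, butterfly = 1),
    plant_locations = "all"
  )
  recs <- sample_visits(comm, dry_only, seed = 87)
  expect_false(any(recs$plant %in% brief))
  expect_true(any(recs$plant %in% setdiff(comm$plants, brief)))
})

test_that("identical (community, design, seed) reproduce records exactly", {
  comm <- generate_community(4, 8, 2, seed = 88, n_continuous = 4)
  des <- deep_design(3)
  expect_identical(sample_visits(comm, des, seed = 89),
                   sample_visits(comm, des, seed = 89))
  expect_false(identical(sample_visits(comm, des, seed = 89),
                         sample_visits(comm, des, seed = 90)))
})

test_that("partition agreement is an NMI with the stated conventions", {
  p <- module_partition(c(1, 1, 2, 2), c(1, 2, 2, 1))
  expect_equal(partition_agreement(p, p), 1)
  relab <- module_partition(c(2, 2, 1, 1), c(2, 1, 1, 2))
  expect_equal(partition_agreement(p, relab), 1)

  all_one <- module_partition(rep(1, 4), rep(1, 4))
  singletons <- module_partition(1:4, 5:8)
  expect_equal(partition_agreement(all_one, singletons), 0)
  expect_equal(partition_agreement(all_one, all_one), 1)

  short <- module_partition(c(1, 2), c(1, 2))
  expect_error(partition_agreement(p, short), "node set")
})

test_that("partition agreement aligns nodes by name when available", {
  a <- module_partition(setNames(c(1L, 2L), c("r1", "r2")),
                        setNames(c(1L, 2L), c("c1", "c2")))
  b <- module_partition(setNames(c(2L, 1L), c("r2", "r1")),
                        setNames(c(2L, 1L), c("c2", "c1")))
  expect_equal(partition_agreement(a, b), 1)
})

test_that("truth sidecar is written next to the records", {
  comm <- generate_community(3, 5, 2, seed = 91, connector_count = 1,
                             n_continuous = 3)
  recs <- sample_visits(comm, deep_design(3), seed = 92)
  path <- tempfile(fileext = ".csv")
  write_synthetic(recs, comm, path)
  truth <- jsonlite::read_json(paste0(sub("\\.csv$", "", path),
                                      "_truth.json"))
  expect_equal(truth$n_modules, 2)
  expect_equal(length(truth$plant_module), 3)
  expect_equal(unlist(truth$planted_connectors), comm$planted_connectors)
  expect_true(file.exists(path))
})

test_that("strong planted structure is recovered end to end", {
  comm <- generate_community(6, 12, 3, lambda_in = 2, lambda_out = 0.1,
                             seed = 93, n_continuous = 6)
  recs <- sample_visits(comm, deep_design(20), seed = 94)
  mat <- build_matrix(recs)
  opt <- optimize_modules(mat, n_restarts = 10, seed = 95)
  expect_gte(partition_agreement(opt$partition, truth_for_matrix(comm, mat)),
             0.9)
})
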