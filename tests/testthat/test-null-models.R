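test_that("a 1x1 matrix has a single null configuration", {
  m <- interaction_matrix(matrix(5L, 1, 1))
  withr::with_seed(1, {
    for (i in 1:5) expect_equal(unname(vaznull_sample(m)$A[1, 1]), 5L)
  })
})

test_that("2x2 diagonal nulls only use full-coverage two-cell skeletons", {
  m <- interaction_matrix(matrix(c(3L, 0L, 0L, 3L), 2, 2))
  withr::with_seed(2, {
    seen <- replicate(100, {
      s <- vaznull_sample(m)
      expect_equal(s$total, 6L)
      expect_equal(s$fill, 2L)
      expect_true(all(s$k >= 1) && all(s$d >= 1))
      paste(sort(which(s$A > 0)), collapse = ",")
    })
  })
  # only the main diagonal {1,4} and anti-diagonal {2,3} cover both rows
  # and both columns with two cells
  expect_true(all(seen %in% c("1,4", "2,3")))
  expect_equal(length(unique(seen)), 2L)
})

test_that("nulls preserve total, fill and margin coverage across matrices", {
  set.seed(3)
  for (rep in 1:5) {
    m <- random_small_matrix(max_dim = 5, max_cell = 6)
    for (i in 1:40) {
      s <- vaznull_sample(m)
      expect_identical(dim(s$A), dim(m$A))
      expect_equal(s$total, m$total)
      expect_equal(s$fill, m$fill)
      expect_true(all(s$k >= 1))
      expect_true(all(s$d >= 1))
    }
  }
})

test_that("an unsatisfiable skeleton is rejected, naming the constraint", {
  # cannot arise from a valid constructor (every row/column has a filled
  # cell), so exercise the guard on a hand-built degenerate object
  broken <- structure(
    list(A = matrix(c(4L, 0L), 2, 1), row_labels = c("a", "b"),
         col_labels = "p", k = c(4, 0), d = 4, total = 4L, fill = 1L),
    class = "interaction_matrix"
  )
  expect_error(vaznull_sample(broken), "unsatisfiable skeleton")
})

test_that("null_ensemble is reproducible from its seed and differs across seeds", {
  m <- block_matrix(2, weight = 3L)
  e1 <- null_ensemble(m, n = 10, seed = 11, n_restarts = 5)
  e2 <- null_ensemble(m, n = 10, seed = 11, n_restarts = 5)
  e3 <- null_ensemble(m, n = 10, seed = 12, n_restarts = 5)
  expect_identical(e1$q_null, e2$q_null)
  expect_identical(e1$pooled_c, e2$pooled_c)
  expect_identical(e1$pooled_z, e2$pooled_z)
  expect_false(identical(e1$q_null, e3$q_null))
  expect_length(e1$q_null, 10)
  expect_error(null_ensemble(m, n = 1, seed = 1), ">= 2")
})

test_that("a strongly modular matrix exceeds its null modularity", {
  m <- block_matrix(3, block = 3L, weight = 4L)
  q_obs <- optimize_modules(m, n_restarts = 10, seed = 21)$Q
  ens <- null_ensemble(m, n = 30, seed = 22, n_restarts = 10)
  expect_gt(q_obs, mean(ens$q_null))
})

test_that("modularity_z_score arithmetic and strict significance rule", {
  fake <- structure(
    list(n = 3L, q_null = c(0.2, 0.3, 0.4), pooled_c = 0.1, pooled_z = 0,
         seed = 1L, n_restarts = 1L, level = "plant"),
    class = "null_ensemble"
  )
  z <- modularity_z_score(0.5, fake)
  expect_equal(z$Z_Q, 2)
  expect_false(z$significant)  # strictly greater than 2 required
  expect_equal(z$Q_adjusted, 0.2)

  z0 <- modularity_z_score(0.3, fake)
  expect_equal(z0$Z_Q, 0)
  expect_equal(z0$Q_adjusted, 0)

  degen <- structure(
    list(n = 2L, q_null = c(0.3, 0.3), pooled_c = 0, pooled_z = 0,
         seed = 1L, n_restarts = 1L, level = "plant"),
    class = "null_ensemble"
  )
  zi <- modularity_z_score(0.4, degen)
  expect_identical(zi$Z_Q, Inf)
  expect_true(zi$significant)
  expect_error(modularity_z_score(0.2, degen), "undefined")
})

test_that("null sd uses the sample (n-1) convention", {
  fake <- structure(
    list(n = 2L, q_null = c(0.2, 0.4), pooled_c = 0, pooled_z = 0,
         seed = 1L, n_restarts = 1L, level = "plant"),
    class = "null_ensemble"
  )
  z <- modularity_z_score(0.5, fake)
  expect_equal(z$Q_null_sd, sd(c(0.2, 0.4)))
})

test_that("a vaznull draw treated as observed shows no self-significance", {
  base <- withr::with_seed(31, {
    interaction_matrix(matrix(rpois(48, 6) + 1L, 6, 8))
  })
  z <- vapply(1:50, function(s) {
    obs <- withr::with_seed(s, vaznull_sample(base))
    opt <- optimize_modules(obs, n_restarts = 5, seed = s + 100)
    ens <- null_ensemble(obs, n = 12, seed = s + 200, n_restarts = 5)
    modularity_z_score(opt, ens)$Z_Q
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.5)
})

test_that("ensemble summary JSON round-trips the Z_Q fields", {
  m <- block_matrix(2, weight = 2L)
  ens <- null_ensemble(m, n = 5, seed = 3, n_restarts = 5)
  zq <- modularity_z_score(optimize_modules(m, 5, 4), ens)
  path <- tempfile(fileext = ".json")
  tsv <- tempfile(fileext = ".tsv")
  write_ensemble_summary(zq, ens, path, q_null_path = tsv)
  back <- jsonlite::read_json(path)
  expect_equal(back$Z_Q, zq$Z_Q)
  expect_equal(back$n, 5)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 5)
})
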