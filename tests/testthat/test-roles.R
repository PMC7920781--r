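test_that("species strength matches hand-evaluated dependencies", {
  # rows = pollinators: [[2,0],[1,1]]
  m <- interaction_matrix(matrix(c(2L, 1L, 0L, 1L), 2, 2))
  expect_equal(unname(species_strength(m, "plant")), c(1.5, 0.5))

  ident <- interaction_matrix(matrix(c(5L, 0L, 0L, 7L), 2, 2))
  expect_equal(unname(species_strength(ident, "plant")), c(1, 1))
})

test_that("strengths of one level sum to the size of the other level", {
  set.seed(501)
  for (i in 1:15) {
    m <- random_small_matrix(max_dim = 5)
    expect_equal(sum(species_strength(m, "plant")), nrow(m$A))
    expect_equal(sum(species_strength(m, "pollinator")), ncol(m$A))
  }
})

test_that("participation c matches closed forms", {
  # all partners in one module -> c = 0
  m <- interaction_matrix(matrix(c(2L, 1L, 0L, 1L), 2, 2))
  p_one <- module_partition(c(1, 1), c(1, 2))
  expect_equal(unname(participation_c(m, p_one, "plant")), c(0, 0))

  # plant with partner-module strengths (1.0, 0.5): c = 4/9
  p_split <- module_partition(c(1, 2), c(1, 2))
  expect_equal(unname(participation_c(m, p_split, "plant"))[1], 4 / 9)

  # equal split over T modules -> c = 1 - 1/T
  for (T in 2:4) {
    A <- matrix(1L, T, 1)
    mT <- interaction_matrix(A)
    pT <- module_partition(seq_len(T), 1L)
    expect_equal(unname(participation_c(mT, pT, "plant")), 1 - 1 / T)
  }
})

test_that("c and z are invariant to module relabeling and c stays in [0,1)", {
  set.seed(502)
  for (i in 1:10) {
    m <- random_small_matrix(max_dim = 4)
    nr <- nrow(m$A); nc <- ncol(m$A)
    labs <- sample.int(3, nr + nc, replace = TRUE)
    perm <- sample.int(3)
    p1 <- module_partition(labs[seq_len(nr)], labs[nr + seq_len(nc)])
    p2 <- module_partition(perm[labs[seq_len(nr)]],
                           perm[labs[nr + seq_len(nc)]])
    c1 <- participation_c(m, p1, "plant")
    expect_equal(c1, participation_c(m, p2, "plant"))
    expect_true(all(c1 >= 0 & c1 < 1))
    expect_equal(within_module_z(m, p1, "plant"),
                 within_module_z(m, p2, "plant"))
  }
})

test_that("strength decomposition by partner module is exact", {
  set.seed(503)
  for (i in 1:10) {
    m <- random_small_matrix(max_dim = 4)
    nr <- nrow(m$A); nc <- ncol(m$A)
    labs <- sample.int(2, nr + nc, replace = TRUE)
    p <- module_partition(labs[seq_len(nr)], labs[nr + seq_len(nc)])
    W <- pollinet:::strength_by_partner_module(m, p, "plant")
    expect_equal(unname(colSums(W)), unname(species_strength(m, "plant")))
  }
})

test_that("within-module z standardizes to mean 0 / sample sd 1", {
  # two plants with within-module strengths {2, 4}
  m <- interaction_matrix(rbind(c(2L, 4L)))
  p <- module_partition(1L, c(1L, 1L))
  z <- within_module_z(m, p, "plant")
  expect_equal(unname(z), c(-1, 1) / sqrt(2))

  # a plant exactly at its module mean gets z = 0
  m3 <- interaction_matrix(rbind(c(1L, 2L, 3L)))
  z3 <- within_module_z(m3, module_partition(1L, c(1L, 1L, 1L)), "plant")
  expect_equal(unname(z3)[2], 0)

  # single-plant module -> z = 0 by convention
  m1 <- interaction_matrix(matrix(c(2L, 1L, 0L, 1L), 2, 2))
  z1 <- within_module_z(m1, module_partition(c(1, 2), c(1, 2)), "plant")
  expect_equal(unname(z1), c(0, 0))
})

test_that("z has mean 0 and sd 1 within every non-degenerate module", {
  set.seed(504)
  m <- interaction_matrix(matrix(rpois(40, 3) + 1L, 5, 8))
  p <- module_partition(sample.int(2, 5, replace = TRUE),
                        rep(c(1L, 2L), each = 4))
  z <- within_module_z(m, p, "plant")
  for (mod in 1:2) {
    zm <- z[p$col_module == mod]
    expect_equal(mean(zm), 0)
    expect_equal(sd(zm), 1)
  }
})

test_that("critical thresholds use the type-7 linear-interpolation quantile", {
  ens <- structure(
    list(n = 100L, q_null = numeric(100), pooled_c = rep(0.3, 50),
         pooled_z = as.numeric(1:100), seed = 1L, n_restarts = 1L,
         level = "plant"),
    class = "null_ensemble"
  )
  thr <- critical_thresholds(ens, 0.95)
  expect_equal(thr$z_critical, 95.05)
  expect_equal(thr$c_critical, 0.3)

  ens$pooled_z <- c(0, 1)
  expect_equal(critical_thresholds(ens, 0.5)$z_critical, 0.5)
  expect_error(critical_thresholds(ens, 1), "quantile")
  expect_error(critical_thresholds(ens, 0), "quantile")
})

test_that("role quadrants follow the strict-inequality rules", {
  thr <- structure(
    list(c_critical = 0.6, z_critical = 2.0, quantile = 0.95,
         n_nulls = 100L, quantile_method = "type7"),
    class = "role_thresholds"
  )
  scores <- tibble::tibble(
    species = c("conn", "peri", "nhub", "mhub", "edge_c", "edge_z"),
    module = 1L,
    strength = 1,
    c = c(0.8, 0.1, 0.7, 0.2, 0.6, 0.3),
    z = c(0.5, 0.1, 2.5, 2.6, 1.0, 2.0)
  )
  roles <- assign_roles(scores, thr)
  expect_equal(
    as.character(roles$role),
    c("connector", "peripheral", "network_hub", "module_hub",
      "peripheral",   # c == c_critical falls to the non-exceeding side
      "peripheral")   # z == z_critical likewise
  )
})

test_that("the four roles are mutually exclusive and exhaustive", {
  thr <- structure(
    list(c_critical = 0.5, z_critical = 0.5, quantile = 0.95,
         n_nulls = 10L, quantile_method = "type7"),
    class = "role_thresholds"
  )
  set.seed(505)
  scores <- tibble::tibble(
    species = sprintf("s%d", 1:200), module = 1L, strength = 1,
    c = runif(200), z = rnorm(200)
  )
  roles <- assign_roles(scores, thr)
  expect_false(anyNA(roles$role))
  expect_equal(nrow(roles), 200)
})

test_that("role_scores assembles a coherent table for a block network", {
  m <- block_matrix(3, block = 3L, weight = 2L)
  opt <- optimize_modules(m, n_restarts = 10, seed = 51)
  sc <- role_scores(m, opt$partition, "plant")
  expect_setequal(names(sc), c("species", "module", "strength", "c", "z"))
  # pure block structure: every plant interacts only inside its module
  expect_true(all(sc$c == 0))
})
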