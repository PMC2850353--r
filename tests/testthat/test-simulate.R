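test_that("zero branch lengths give an all-constant matrix", {
  cfg <- sim_config(n_taxa = 6, branch_length = 0, n_sites = 50, n_morph = 10,
                    n_indel = 3, missing_fraction = 0,
                    polymorphic_fraction = 0)
  sim <- simulate_matrix(cfg, seed = 2)
  st <- matrix_stats(sim$matrix)
  expect_equal(sum(st$n_variable), 0L)
})

test_that("simulation is deterministic under config + seed", {
  cfg <- sim_config(n_taxa = 6, n_sites = 40, n_morph = 10, n_indel = 4)
  a <- simulate_matrix(cfg, seed = 9)
  b <- simulate_matrix(cfg, seed = 9)
  expect_identical(cell_strings(a$matrix), cell_strings(b$matrix))
  expect_true(same_topology(a$tree, b$tree))
})

test_that("simulated base composition converges to the configured frequencies", {
  cfg <- sim_config(n_taxa = 4, branch_length = 0.2, n_sites = 50000,
                    n_morph = 0, n_indel = 0, missing_fraction = 0,
                    polymorphic_fraction = 0, gamma_shape = NULL)
  sim <- simulate_matrix(cfg, seed = 21)
  cs <- cell_strings(sim$matrix)
  obs <- table(factor(cs, levels = c("A", "C", "G", "T"))) / length(cs)
  expect_lt(max(abs(as.numeric(obs) -
                      unname(cfg$base_frequencies))), 0.01)
})

test_that("the injected missing fraction is realized within binomial tolerance", {
  cfg <- sim_config(n_taxa = 8, n_sites = 400, n_morph = 50, n_indel = 10,
                    missing_fraction = 0.15, polymorphic_fraction = 0)
  sim <- simulate_matrix(cfg, seed = 3)
  frac <- mean(sim$matrix$masks == 0L)
  n <- length(sim$matrix$masks)
  expect_lt(abs(frac - 0.15), 4 * sqrt(0.15 * 0.85 / n))
})

test_that("MP search recovers the generating topology at generous settings", {
  cfg <- sim_config(n_taxa = 8, branch_length = 0.1, n_sites = 2000,
                    n_morph = 0, n_indel = 0, missing_fraction = 0,
                    polymorphic_fraction = 0)
  sim <- simulate_matrix(cfg, seed = 7)
  h <- heuristic_search(sim$matrix, n_replicates = 5, seed = 7)
  expect_equal(length(h$trees), 1L)
  expect_true(same_topology(h$trees[[1]], ape::unroot(sim$tree)))
})

test_that("topology recovery does not degrade with more sites", {
  hits <- function(n_sites, seeds) {
    sum(vapply(seeds, function(s) {
      cfg <- sim_config(n_taxa = 8, branch_length = 0.08, n_sites = n_sites,
                        n_morph = 0, n_indel = 0, missing_fraction = 0,
                        polymorphic_fraction = 0)
      sim <- simulate_matrix(cfg, seed = s)
      h <- heuristic_search(sim$matrix, n_replicates = 3, seed = s)
      as.numeric(length(h$trees) == 1L &&
                   same_topology(h$trees[[1]], ape::unroot(sim$tree)))
    }, numeric(1)))
  }
  seeds <- 101:115
  expect_gte(hits(2000, seeds), hits(200, seeds))
})

test_that("the shipped fixture equals its generator and survives a round trip", {
  fx <- make_mixed_fixture(42)
  shipped <- fixture_matrix()
  expect_identical(cell_strings(shipped), cell_strings(fx$matrix))
  expect_identical(shipped$datatype, fx$matrix$datatype)
  expect_equal(names(shipped$partitions), c("GHR", "morphology", "indels"))
  # exhaustive and heuristic agree on the fixture's optimum
  ex <- exhaustive_search(shipped)
  h <- heuristic_search(shipped, n_replicates = 5, seed = 8)
  expect_equal(h$best_length, ex$best_length)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(base_frequencies = c(A = 1, C = 0, G = 0, T = 0.2)),
               "sum to 1")
  expect_error(sim_config(kappa = -1), "positive")
  expect_error(sim_config(missing_fraction = 1.5), "\\[0, 1\\]")
})
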