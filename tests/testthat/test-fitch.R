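test_that("single-origin and constant characters score as expected", {
  cells <- rbind(A = c("A", "C"), B = c("A", "C"), C = c("G", "C"),
                 D = c("G", "C"))
  m <- char_matrix(cells, datatype = "dna")
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  rep <- fitch_length(tr, m)
  expect_equal(rep$per_character_steps, c(1L, 0L))
  expect_equal(rep$total_steps, 1L)
})

test_that("4-taxon incongruent character needs two steps", {
  cells <- rbind(A = "0", B = "1", C = "0", D = "1")
  m <- char_matrix(cells)
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(brute_force_length(tr, m), 2L)
  expect_equal(fitch_length(tr, m)$total_steps, 2L)
})

test_that("Fitch equals brute-force enumeration on random small instances", {
  withr::with_seed(101, {
    for (i in 1:60) {
      n <- sample(4:6, 1)
      m <- random_standard_matrix(n, 8, n_states = sample(2:4, 1))
      tr <- random_unrooted_tree(m$taxa)
      expect_equal(fitch_length(tr, m)$total_steps, brute_force_length(tr, m))
    }
  })
})

test_that("Fitch agrees with an independent parsimony implementation", {
  withr::with_seed(55, {
    for (i in 1:10) {
      n <- 8
      cells <- matrix(as.character(sample(0:2, n * 20, TRUE)), n, 20,
                      dimnames = list(paste0("t", 1:n), NULL))
      m <- char_matrix(cells, datatype = "standard")
      tr <- random_unrooted_tree(m$taxa)
      pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1", "2"))
      expect_equal(fitch_length(tr, m)$total_steps,
                   as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
    }
  })
})

test_that("brute force refuses instances beyond its size bound", {
  withr::with_seed(9, {
    m <- random_standard_matrix(9, 3)
    expect_error(brute_force_length(random_unrooted_tree(m$taxa), m),
                 "8 leaves")
  })
})

test_that("lengths are additive over partitions and per-character steps", {
  withr::with_seed(77, {
    fx <- fixture_matrix()
    tr <- random_unrooted_tree(fx$taxa)
    rep <- fitch_length(tr, fx)
    expect_equal(sum(rep$per_partition_steps), rep$total_steps)
    expect_equal(sum(rep$per_character_steps), rep$total_steps)
    for (p in names(fx$partitions)) {
      expect_equal(partition_length(tr, fx, p),
                   unname(rep$per_partition_steps[p]))
    }
  })
})

test_that("adding characters never decreases length; dropping taxa never increases it", {
  withr::with_seed(13, {
    m <- random_standard_matrix(7, 10, n_states = 3)
    tr <- random_unrooted_tree(m$taxa)
    full <- fitch_length(tr, m)$total_steps
    m_half <- char_matrix(cell_strings(m)[, 1:5, drop = FALSE],
                          datatype = m$datatype[1:5])
    expect_lte(fitch_length(tr, m_half)$total_steps, full)

    kept <- m$taxa[1:5]
    sub_tree <- ape::drop.tip(tr, setdiff(m$taxa, kept))
    expect_lte(fitch_length(sub_tree, m)$total_steps, full)
  })
})

test_that("polymorphism accounting charges at least the uncertainty length", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- 6
      cells <- matrix(as.character(sample(0:2, n * 6, TRUE)), n, 6,
                      dimnames = list(paste0("t", 1:n), NULL))
      # sprinkle multi-state cells
      hits <- sample(length(cells), 5)
      cells[hits] <- vapply(cells[hits], function(x) {
        paste0(sort(unique(c(x, sample(0:2, 1)))), collapse = "")
      }, character(1))
      m <- char_matrix(cells, datatype = "standard")
      tr <- random_unrooted_tree(m$taxa)
      u <- fitch_length(tr, m, mode = "uncertainty")$total_steps
      p <- fitch_length(tr, m, mode = "polymorphism")$total_steps
      expect_gte(p, u)
    }
    # equality when no multi-state cells
    m0 <- random_standard_matrix(6, 8)
    tr0 <- random_unrooted_tree(m0$taxa)
    expect_equal(fitch_length(tr0, m0, mode = "polymorphism")$total_steps,
                 fitch_length(tr0, m0, mode = "uncertainty")$total_steps)
  })
})

test_that("missing data never forces steps", {
  cells <- rbind(A = "0", B = "?", C = "0", D = "?")
  m <- char_matrix(cells)
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_length(tr, m)$total_steps, 0L)
})

test_that("scoring errors on leaves absent from the matrix", {
  m <- random_standard_matrix(4, 3)
  tr <- ape::read.tree(text = "((t1,t2),(t3,zzz));")
  expect_error(fitch_length(tr, m), "absent from matrix")
})
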