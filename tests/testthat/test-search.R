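test_that("exhaustive search scores exactly 3 topologies for 4 taxa", {
  withr::with_seed(2, {
    m <- random_standard_matrix(4, 6)
    ex <- exhaustive_search(m)
    expect_equal(ex$n_scored, 3)
  })
})

test_that("exhaustive search refuses more than 9 taxa with the topology count", {
  withr::with_seed(2, {
    m <- random_standard_matrix(10, 4)
    expect_error(exhaustive_search(m), "2,027,025")
  })
})

test_that("heuristic search attains the exhaustive optimum on random instances", {
  withr::with_seed(23, {
    for (i in 1:25) {
      n <- sample(6:8, 1)
      m <- random_standard_matrix(n, 12, n_states = 2)
      ex <- exhaustive_search(m)
      h <- heuristic_search(m, n_replicates = 5, seed = i)
      expect_equal(h$best_length, ex$best_length)
    }
  })
})

test_that("compatible characters on a known tree give that tree as unique optimum", {
  withr::with_seed(4, {
    true <- random_unrooted_tree(paste0("t", 1:8))
    m <- compatible_matrix(true, per_edge = 3)
    ex <- exhaustive_search(m)
    expect_equal(length(ex$trees), 1L)
    expect_true(same_topology(ex$trees[[1]], true))
    # optimum = one step per character (single origin each)
    expect_equal(ex$best_length, n_char(m))
    h <- heuristic_search(m, n_replicates = 3, seed = 1)
    expect_equal(h$best_length, ex$best_length)
  })
})

test_that("search is deterministic under a fixed seed", {
  withr::with_seed(6, {
    m <- random_standard_matrix(7, 10)
  })
  h1 <- heuristic_search(m, n_replicates = 4, seed = 99)
  h2 <- heuristic_search(m, n_replicates = 4, seed = 99)
  expect_identical(h1$best_length, h2$best_length)
  expect_identical(lapply(h1$trees, ape::write.tree),
                   lapply(h2$trees, ape::write.tree))
})

test_that("collapsing is idempotent and retained branches have min length >= 1", {
  withr::with_seed(41, {
    m <- random_standard_matrix(7, 8)
    h <- heuristic_search(m, n_replicates = 4, seed = 3, collapse = FALSE)
    for (bt in h$binary_trees) {
      c1 <- collapse_minbrlen(bt, m)
      n <- length(bt$tip.label)
      # every retained internal branch of the binary tree has min >= 1
      bs <- branch_steps(bt, m)
      kept <- bs$min_steps[bs$child > n]
      c1_internal <- sum(c1$edge[, 2] > n)
      expect_equal(c1_internal, sum(kept >= 1L))
      # idempotence on an already-collapsed binary tree
      if (parsmix:::is_binary_unrooted(c1)) {
        c2 <- collapse_minbrlen(c1, m)
        expect_equal(parsmix:::topology_key(c2), parsmix:::topology_key(c1))
      }
    }
  })
})

test_that("optimal trees are pairwise distinct by bipartition set and all score best", {
  withr::with_seed(12, {
    m <- random_standard_matrix(7, 9)
    h <- heuristic_search(m, n_replicates = 5, seed = 2)
    keys <- vapply(h$trees, parsmix:::topology_key, character(1))
    expect_equal(anyDuplicated(keys), 0L)
    for (bt in h$binary_trees) {
      expect_equal(fitch_length(bt, m)$total_steps, h$best_length)
    }
  })
})

test_that("constrained searches honour positive and converse clade constraints", {
  withr::with_seed(10, {
    true <- random_unrooted_tree(paste0("t", 1:7))
    m <- compatible_matrix(true, per_edge = 2)
    keys <- parsmix:::tree_split_keys(true, sort(true$tip.label))
    clade <- strsplit(keys[1], ";", fixed = TRUE)[[1]]

    pos <- heuristic_search(m, n_replicates = 4, seed = 5,
                            constraint = clade_constraint(clade))
    expect_true(all(vapply(pos$binary_trees, has_clade, logical(1),
                           clade = clade)))

    con <- heuristic_search(m, n_replicates = 4, seed = 5,
                            constraint = clade_constraint(clade,
                                                          converse = TRUE))
    expect_false(any(vapply(con$binary_trees, has_clade, logical(1),
                            clade = clade)))
    # forbidding a supported clade must cost extra steps
    expect_gt(con$best_length, heuristic_search(m, 2, seed = 5)$best_length)
  })
})

test_that("searches with fewer than 4 taxa return the trivial topology", {
  cells <- rbind(a = c("0", "1"), b = c("1", "1"))
  m <- char_matrix(cells)
  res <- heuristic_search(m, n_replicates = 2, seed = 1)
  expect_equal(res$best_length, 1L)
  expect_match(res$note, "fewer than 4 taxa")
})

test_that("strict consensus keeps only shared clades; majority keeps >cutoff", {
  t1 <- ape::read.tree(text = "((A,B),C,D);")
  t2 <- ape::read.tree(text = "((A,C),B,D);")
  # identical trees in -> same tree out
  same <- consensus_tree(c(t1, t1), method = "strict")
  expect_true(same_topology(same$tree, t1))
  # conflicting clade collapses to a polytomy under strict
  st <- consensus_tree(c(t1, t2), method = "strict")
  expect_equal(st$tree$Nnode, 1L)
  # 2-of-3 majority retains (A,B)
  mj <- consensus_tree(c(t1, t1, t2), method = "majority", cutoff = 50)
  expect_true(has_clade(mj$tree, c("A", "B")))
  freq <- tidy(mj)
  expect_equal(freq$frequency[freq$clade == "C;D"], 2 / 3)
})

test_that("strict consensus clades appear in every input tree", {
  # only {t1,t2} is supported, so many optimal resolutions exist
  taxa <- paste0("t", 1:6)
  cells <- matrix("0", 6, 6, dimnames = list(taxa, NULL))
  cells[1:2, 1:4] <- "1"
  m <- char_matrix(cells)
  h <- heuristic_search(m, n_replicates = 4, seed = 7, collapse = FALSE)
  expect_gt(length(h$binary_trees), 1L)
  cs <- consensus_tree(h$binary_trees, method = "strict")
  expect_true(has_clade(cs$tree, c("t1", "t2")))
  for (k in parsmix:::tree_split_keys(cs$tree, taxa)) {
    expect_true(all(vapply(h$binary_trees, function(t) {
      k %in% parsmix:::tree_split_keys(t, taxa)
    }, logical(1))))
  }
})

test_that("bootstrap ranks a strongly supported clade first", {
  withr::with_seed(14, {
    taxa <- paste0("t", 1:8)
    cells <- matrix("0", 8, 30, dimnames = list(taxa, NULL))
    cells[5:8, 1:20] <- "1"
    cells[, 21:30] <- replicate(10, as.character(sample(0:1, 8, TRUE)))
    m <- char_matrix(cells, datatype = "standard")
    bs <- bootstrap_support(m, n_pseudoreplicates = 30, seed = 4)
    expect_equal(bs$clade[1], "t5;t6;t7;t8")
    expect_true(all(bs$support[1] >= bs$support))
    expect_true(all(bs$reported == (bs$support >= 50)))
  })
})

test_that("a matrix with no informative characters gives no clade above 50", {
  withr::with_seed(19, {
    taxa <- paste0("t", 1:6)
    cells <- matrix("0", 6, 10, dimnames = list(taxa, NULL))
    for (j in 1:10) cells[sample(6, 1), j] <- "1"   # autapomorphies only
    m <- char_matrix(cells)
    bs <- bootstrap_support(m, n_pseudoreplicates = 20, seed = 3)
    expect_true(all(bs$support < 50) || nrow(bs) == 0L)
    expect_error(bootstrap_support(m, n_pseudoreplicates = 0),
                 "at least one pseudoreplicate")
  })
})
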