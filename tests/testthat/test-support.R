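test_that("HBS arithmetic identity holds and errors on missing PBS", {
  expect_equal(hidden_branch_support(47, c(14, 13, 0)), 20)
  expect_equal(hidden_branch_support(1, c(1, -2, 0)), 2)
  expect_equal(hidden_branch_support(0, c(0, 0, 0)), 0)
  expect_error(hidden_branch_support(5, c(1, NA)), "every partition")
})

test_that("published golden-mole support table satisfies HBS = BS - sum(PBS) on all 23 rows", {
  tab <- chrysochloridae_support_table()
  expect_equal(nrow(tab), 23L)
  expect_equal(tab$comb_bs, tab$comb_wo - tab$comb)
  expect_equal(tab$hbs,
               tab$comb_bs - (tab$ghr_bs + tab$morph_bs + tab$indel_bs))
  # spot values: clades a and b
  expect_equal(tab$comb_wo[tab$node == "a"], 970)
  expect_equal(tab$comb_bs[tab$node == "a"], 13)
  expect_equal(tab$comb_wo[tab$node == "b"], 1004)
  expect_equal(tab$comb_bs[tab$node == "b"], 47)
  expect_equal(tab$ghr_bs[tab$node == "b"], 14)
  expect_equal(tab$morph_bs[tab$node == "b"], 13)
  expect_equal(tab$indel_bs[tab$node == "b"], 0)
  expect_equal(tab$hbs[tab$node == "b"], 20)
})

test_that("Bremer support equals the number of characters that must be overturned", {
  # 5 compatible characters support {t1,t2,t3}; forbidding the clade forces
  # each of them onto a second step, verified against exhaustive search
  cells <- matrix("0", 6, 8, dimnames = list(paste0("t", 1:6), NULL))
  cells[1:3, 1:5] <- "1"
  cells[1:2, 6:8] <- "1"
  m <- char_matrix(cells)
  ex <- exhaustive_search(m)
  br <- bremer_support(m, c("t1", "t2", "t3"), n_replicates = 6, seed = 2)
  expect_equal(br$comb, ex$best_length)
  expect_equal(br$bs, 5L)
  expect_equal(br$comb_wo, ex$best_length + 5L)
})

test_that("clade arguments are validated", {
  withr::with_seed(3, m <- random_standard_matrix(6, 6))
  expect_error(bremer_support(m, m$taxa), "2 to n-2")
  expect_error(bremer_support(m, "t1"), "2 to n-2")
})

test_that("conflicting partitions give opposite-signed PBS on the disputed clade", {
  # partition one supports {t1..t4}; partition two supports {t3..t6}
  taxa <- paste0("t", 1:8)
  cells <- matrix("0", 8, 14, dimnames = list(taxa, NULL))
  cells[1:4, 1:6] <- "1"        # p1: 6 chars for clade A = t1-t4
  cells[3:6, 7:10] <- "1"       # p2: 4 chars for conflicting clade B = t3-t6
  cells[7:8, 11:14] <- "1"      # shared signal elsewhere
  m <- char_matrix(cells, partitions = list(p1 = 1:6, p2 = 7:14))
  tabA <- clade_row(m, c("t1", "t2", "t3", "t4"))
  expect_gt(tabA$p1_bs, 0)
  expect_lt(tabA$p2_bs, 0)
})

test_that("build_support_table rows match individual calls and satisfy the identity", {
  withr::with_seed(28, {
    fx <- fixture_matrix()
    baseline <- heuristic_search(fx, n_replicates = 6, seed = 11)
    cons <- consensus_tree(baseline$binary_trees, method = "strict")
    keys <- parsmix:::tree_split_keys(cons$tree, sort(fx$taxa))
    clades <- lapply(keys, function(k) strsplit(k, ";", fixed = TRUE)[[1]])
    names(clades) <- letters[seq_along(clades)]
    tab <- build_support_table(fx, clades, n_replicates = 6, seed = 11,
                               baseline = baseline)
    expect_equal(nrow(tab), length(clades))
    # identity on every emitted row
    pbs <- tab$GHR_bs + tab$morphology_bs + tab$indels_bs
    expect_equal(tab$hbs, tab$bs - pbs)
    # strict-consensus clades have BS >= 1
    expect_true(all(tab$bs >= 1L))
    # single-clade call agrees with the table row
    one <- bremer_support(fx, clades[[1]], n_replicates = 6, seed = 11,
                          baseline = baseline)
    expect_equal(one$bs, tab$bs[1])
    expect_equal(one$comb_wo, tab$comb_wo[1])
  })
})

test_that("a partition with no variable characters contributes zero PBS", {
  taxa <- paste0("t", 1:6)
  cells <- matrix("0", 6, 10, dimnames = list(taxa, NULL))
  cells[1:3, 1:6] <- "1"
  # characters 7-10 constant
  m <- char_matrix(cells, partitions = list(var = 1:6, flat = 7:10))
  row <- clade_row(m, c("t1", "t2", "t3"))
  expect_equal(row$flat_bs, 0)
})
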