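test_that("ACCTRAN places a gain early and a reversal tipward", {
  cells <- rbind(O = "0", X = "1", Y = "0", Z = "1")
  m <- char_matrix(cells, datatype = "standard")
  tr <- ape::unroot(ape::read.tree(text = "(O,(X,(Y,Z)));"))
  bs <- branch_steps(tr, m, outgroup = "O")
  expect_equal(attr(bs, "total_steps"), 2L)
  # the change goes on the ingroup stem, the reversal on Y's terminal branch
  expect_equal(bs$acctran_steps[bs$clade == "X;Y;Z"], 1L)
  expect_equal(bs$acctran_steps[bs$clade == "Y"], 1L)
  expect_equal(sum(bs$acctran_steps), 2L)
})

test_that("ACCTRAN branch steps always sum to the tree length", {
  withr::with_seed(3, {
    for (i in 1:15) {
      m <- random_standard_matrix(8, 15, n_states = 3)
      tr <- random_unrooted_tree(m$taxa)
      bs <- branch_steps(tr, m, outgroup = "t1")
      expect_equal(sum(bs$acctran_steps), fitch_length(tr, m)$total_steps)
      expect_true(all(bs$min_steps <= bs$acctran_steps))
    }
  })
})

test_that("a constant matrix yields all-zero branches", {
  m <- char_matrix(matrix("0", 5, 4, dimnames = list(paste0("t", 1:5), NULL)))
  tr <- random_unrooted_tree(m$taxa)
  bs <- branch_steps(tr, m)
  expect_true(all(bs$acctran_steps == 0L))
  expect_true(all(bs$min_steps == 0L))
})

test_that("per-branch minima match exhaustive enumeration over all MPRs", {
  withr::with_seed(17, {
    for (rep in 1:15) {
      n <- 6
      m <- random_standard_matrix(n, 3, n_states = 3)
      tr <- random_unrooted_tree(m$taxa)
      bs <- branch_steps(tr, m, outgroup = "t1")
      expect_equal(bs$min_steps, brute_branch_minima(tr, m))
    }
  })
})

test_that("branch_steps refuses unresolved trees", {
  m <- random_standard_matrix(5, 4)
  star <- ape::read.tree(text = "(t1,t2,t3,t4,t5);")
  expect_error(branch_steps(star, m), "resolve or collapse")
})
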