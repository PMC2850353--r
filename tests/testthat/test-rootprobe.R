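test_that("random outgroup rows are deterministic and composition-faithful", {
  spec <- random_outgroup_spec()
  r1 <- generate_random_outgroup(spec, seed = 7)
  r2 <- generate_random_outgroup(spec, seed = 7)
  expect_identical(r1, r2)
  expect_length(r1, 913 + 145 + 8)
  expect_true(all(r1[1:913] %in% c("A", "C", "G", "T")))
  expect_true(all(r1[914:1066] %in% c("0", "1")))

  # empirical A-frequency within 3 binomial SDs of 0.28 over many sites
  big <- random_outgroup_spec(n_nucleotides = 100000, n_morphology = 0,
                              n_indel = 0)
  row <- generate_random_outgroup(big, seed = 11)
  pA <- mean(row == "A")
  expect_lt(abs(pA - 0.28), 3 * sqrt(0.28 * 0.72 / 100000))

  # chi-square composition check across all four bases
  obs <- table(factor(row, levels = c("A", "C", "G", "T")))
  pval <- stats::chisq.test(obs, p = c(0.28, 0.27, 0.22, 0.23))$p.value
  expect_gt(pval, 0.01)
})

test_that("DNA-only spec yields a row of bare nucleotides", {
  spec <- random_outgroup_spec(n_nucleotides = 913, n_morphology = 0,
                               n_indel = 0)
  row <- generate_random_outgroup(spec, seed = 1)
  expect_length(row, 913)
  expect_true(all(row %in% c("A", "C", "G", "T")))
})

test_that("spec/matrix layout mismatches are caught unless overridden", {
  withr::with_seed(5, m <- random_standard_matrix(5, 10))
  spec <- random_outgroup_spec()
  expect_error(generate_random_outgroup(spec, m), "do not match")
  row <- generate_random_outgroup(spec, m, seed = 2, override = TRUE)
  expect_length(row, 10)
})

test_that("survey tallies are conserved and reproducible under the master seed", {
  withr::with_seed(44, {
    m <- random_standard_matrix(6, 25, n_states = 2)
  })
  spec <- random_outgroup_spec(n_nucleotides = 0, n_morphology = 20,
                               n_indel = 5)
  sv1 <- survey_root(m, spec, n_outgroups = 8, n_replicates = 3, seed = 5)
  sv2 <- survey_root(m, spec, n_outgroups = 8, n_replicates = 3, seed = 5)
  expect_equal(sum(sv1$counts$count) + sv1$unresolved_count, sv1$n_total)
  expect_identical(sv1$counts, sv2$counts)
  expect_identical(sv1$unresolved_count, sv2$unresolved_count)
  expect_true(all(sv1$replicates$seed == 5 + seq_len(8)))
})

test_that("random outgroups are attracted to a long branch", {
  withr::with_seed(1, {
    taxa <- paste0("t", 1:6)
    cells <- matrix("0", 6, 40, dimnames = list(taxa, NULL))
    cells[, 1:10] <- replicate(10, as.character(sample(0:1, 6, TRUE)))
    cells[1, 11:40] <- "1" # 30 autapomorphies: t1 is the long branch
    m <- char_matrix(cells, datatype = "standard")
  })
  spec <- random_outgroup_spec(n_nucleotides = 0, n_morphology = 35,
                               n_indel = 5)
  sv <- survey_root(m, spec, n_outgroups = 12, n_replicates = 4, seed = 3)
  # modal attachment is t1's terminal branch (keyed by the complement side)
  expect_equal(sv$counts$branch[1], "t2;t3;t4;t5;t6")
  expect_gt(sv$counts$count[1], sv$n_total / 2)
})

test_that("attachment classification distinguishes at/within/other", {
  clades <- list(genus1 = c("s1", "s2"), genus2 = c("s3", "s4", "s5"))
  ingroup <- paste0("s", 1:6)
  expect_equal(classify_attachment(c("s1", "s2"), clades, ingroup),
               "at genus1")
  expect_equal(classify_attachment("s3", clades, ingroup), "within genus2")
  # a branch matching no named clade falls back to its bipartition label
  expect_equal(classify_attachment(c("s2", "s3"), clades, ingroup), "s2;s3")
  # complement side is recognised too
  expect_equal(classify_attachment(setdiff(ingroup, c("s1", "s2")),
                                   clades, ingroup), "at genus1")
})

test_that("summarize_survey groups counts by clade label", {
  withr::with_seed(1, {
    taxa <- paste0("t", 1:6)
    cells <- matrix("0", 6, 30, dimnames = list(taxa, NULL))
    cells[1, 11:30] <- "1"
    cells[, 1:10] <- replicate(10, as.character(sample(0:1, 6, TRUE)))
    m <- char_matrix(cells)
  })
  spec <- random_outgroup_spec(n_nucleotides = 0, n_morphology = 25,
                               n_indel = 5)
  sv <- survey_root(m, spec, n_outgroups = 6, n_replicates = 3, seed = 2)
  sm <- summarize_survey(sv, list(lonely = "t1"))
  expect_equal(sum(sm$count), sv$n_total)
  expect_true("unresolved" %in% sm$label)
})
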