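test_that("NEXUS parsing maps gaps and '?' to missing and keeps polymorphisms", {
  nex <- c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=3 NCHAR=4;",
    "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "  MATRIX",
    "    a ACG-",
    "    b AC?T",
    "    c ARGT",
    "  ;",
    "END;"
  )
  m <- parse_nexus(nex)
  expect_equal(m$taxa, c("a", "b", "c"))
  expect_equal(n_char(m), 4L)
  cs <- cell_strings(m)
  expect_equal(unname(cs["a", 4]), "?")    # gap treated as missing
  expect_equal(unname(cs["b", 3]), "?")
  expect_equal(unname(cs["c", 2]), "AG")   # IUPAC R expanded to a state set
  # every DNA cell is a subset of ACGT or missing
  expect_true(all(grepl("^(\\?|[ACGT]+)$", cs)))
})

test_that("standard-block polymorphic cells like (01) become state sets", {
  nex <- c(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "  DIMENSIONS NTAX=3 NCHAR=2;",
    "  FORMAT DATATYPE=STANDARD;",
    "  MATRIX",
    "    a 0(01)",
    "    b 10",
    "    c {12}1",
    "  ;",
    "END;"
  )
  m <- parse_nexus(nex)
  cs <- cell_strings(m)
  expect_equal(unname(cs["a", 2]), "01")
  expect_equal(unname(cs["c", 1]), "12")
})

test_that("parser reports ragged rows, duplicate taxa and unknown symbols", {
  ragged <- c("#NEXUS", "BEGIN DATA;", "MATRIX", " a 010", " b 01", ";", "END;")
  expect_error(parse_nexus(ragged), "ragged.*\\b(a|b)\\b")
  dup <- c("#NEXUS", "BEGIN DATA;", "MATRIX", " a 010", " a 011", ";", "END;")
  expect_error(parse_nexus(dup), "duplicate taxon label: a")
  bad <- c("#NEXUS", "BEGIN DATA;", "FORMAT DATATYPE=DNA;", "MATRIX",
           " a AJG", " b ACG", ";", "END;")
  expect_error(parse_nexus(bad), "unknown state symbol 'J'")
})

test_that("interleaved matrices, charsets and weights are read", {
  nex <- c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=2 NCHAR=6;",
    "  FORMAT DATATYPE=STANDARD INTERLEAVE;",
    "  MATRIX",
    "    a 010",
    "    b 001",
    "    a 110",
    "    b 111",
    "  ;",
    "END;",
    "BEGIN SETS;",
    "  CHARSET left = 1-3;",
    "  CHARSET right = 4-6;",
    "  WTSET * w = 2: 1 4;",
    "END;",
    "BEGIN PAUP;",
    "  hsearch addseq=random nreps=500;",
    "END;"
  )
  m <- parse_nexus(nex)
  expect_equal(n_char(m), 6L)
  expect_equal(names(m$partitions), c("left", "right"))
  expect_equal(m$weights, c(2L, 1L, 1L, 2L, 1L, 1L))
  expect_equal(unname(cell_strings(m)["a", ]), c("0","1","0","1","1","0"))
})

test_that("NEXUS writer round-trips cells, datatypes, weights and partitions", {
  withr::with_seed(31, {
    fx <- fixture_matrix()
    fx$weights[3] <- 2L
    m2 <- parse_nexus(write_nexus_matrix(fx))
    expect_identical(cell_strings(m2), cell_strings(fx))
    expect_identical(m2$datatype, fx$datatype)
    expect_identical(m2$weights, fx$weights)
    expect_identical(lapply(m2$partitions, as.integer),
                     lapply(fx$partitions, as.integer))
  })
})

test_that("parsimony-informative counting follows the two-states-twice rule", {
  cells <- rbind(A = c("0", "0"), B = c("0", "0"), C = c("1", "0"),
                 D = c("1", "1"))
  m <- char_matrix(cells, datatype = "standard")
  expect_equal(count_parsimony_informative(m), 1L)

  const <- char_matrix(matrix("0", 4, 5,
                              dimnames = list(LETTERS[1:4], NULL)))
  expect_equal(count_parsimony_informative(const), 0L)

  # only the informative character changes the minimum length across topologies
  trees <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                  function(s) ape::read.tree(text = s))
  lens1 <- vapply(trees, function(t) {
    fitch_length(t, subset_one_char(m, 1))$total_steps
  }, numeric(1))
  lens2 <- vapply(trees, function(t) {
    fitch_length(t, subset_one_char(m, 2))$total_steps
  }, numeric(1))
  expect_gt(max(lens1), min(lens1))
  expect_equal(max(lens2), min(lens2))

  # missing/polymorphic cells contribute no occurrences
  cells2 <- rbind(A = "0", B = "01", C = "1", D = "?")
  expect_equal(count_parsimony_informative(char_matrix(cells2)), 0L)
})

test_that("informative count is invariant under taxon and character order", {
  withr::with_seed(5, {
    m <- random_standard_matrix(6, 12, n_states = 3)
    base <- count_parsimony_informative(m)
    perm_t <- sample(n_taxa(m))
    perm_c <- sample(n_char(m))
    m2 <- char_matrix(cell_strings(m)[perm_t, perm_c],
                      datatype = m$datatype[perm_c])
    expect_equal(count_parsimony_informative(m2), base)
  })
})

test_that("partition errors name the offender", {
  m <- fixture_matrix()
  expect_error(count_parsimony_informative(m, "nope"), "unknown partition: nope")
})

test_that("newick writer round-trips topology and serializes branch steps", {
  withr::with_seed(8, {
    tr <- random_unrooted_tree(paste0("t", 1:10))
    txt <- write_newick(tr)
    tr2 <- read_newick(text = txt)
    expect_true(same_topology(tr, tr2))

    steps <- seq_len(nrow(tr$edge))
    txt2 <- write_newick(tr, annotations = steps)
    tr3 <- read_newick(text = txt2)
    expect_equal(sort(tr3$edge.length), sort(as.numeric(steps)))
    expect_error(write_newick(tr, annotations = stats::setNames(1, "999")),
                 "non-existent branch")
  })
})
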