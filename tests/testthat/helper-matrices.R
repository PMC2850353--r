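# Small matrices and trees built in code for the unit tests.

random_standard_matrix <- function(n_taxa, n_char, n_states = 2,
                                   taxa = paste0("t", seq_len(n_taxa))) {
  cells <- matrix(as.character(sample(0:(n_states - 1), n_taxa * n_char,
                                      replace = TRUE)),
                  n_taxa, n_char, dimnames = list(taxa, NULL))
  char_matrix(cells, datatype = "standard")
}

random_unrooted_tree <- function(taxa) {
  ape::unroot(ape::rtree(length(taxa), tip.label = taxa))
}

# perfectly compatible binary characters supporting every internal edge of a
# given unrooted tree, `per_edge` characters per clade
compatible_matrix <- function(tree, per_edge = 2) {
  taxa <- sort(tree$tip.label)
  keys <- parsmix:::tree_split_keys(tree, taxa)
  cols <- list()
  for (k in keys) {
    side <- strsplit(k, ";", fixed = TRUE)[[1]]
    col <- ifelse(tree$tip.label %in% side, "1", "0")
    for (i in seq_len(per_edge)) cols[[length(cols) + 1L]] <- col
  }
  cells <- do.call(cbind, cols)
  rownames(cells) <- tree$tip.label
  char_matrix(cells, datatype = "standard")
}

fixture_matrix <- function() {
  read_nexus_matrix(system.file("extdata", "mixed_fixture.nex",
                                package = "parsmix"))
}

same_topology <- function(a, b) {
  identical(parsmix:::topology_key(a), parsmix:::topology_key(b))
}

subset_one_char <- function(m, j) {
  char_matrix(cell_strings(m)[, j, drop = FALSE], datatype = m$datatype[j])
}

# Per-edge minimum over all most-parsimonious reconstructions by enumeration.
brute_branch_minima <- function(tr, m) {
  edge <- tr$edge
  n <- length(tr$tip.label)
  internal <- sort(unique(edge[, 1]))
  mins <- rep(0L, nrow(edge))
  for (j in seq_len(n_char(m))) {
    masks <- parsmix:::fitch_masks(m, j)[match(tr$tip.label, m$taxa), 1]
    k <- length(m$symbols[[j]])
    assign <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
    costs <- matrix(NA_integer_, nrow(assign), nrow(edge))
    for (r in seq_len(nrow(assign))) {
      st <- integer(max(edge))
      st[internal] <- assign[r, ]
      for (e in seq_len(nrow(edge))) {
        p <- edge[e, 1]
        ch <- edge[e, 2]
        sp <- bitwShiftL(1L, st[p] - 1L)
        costs[r, e] <- if (ch <= n) {
          as.integer(bitwAnd(sp, masks[ch]) == 0L)
        } else {
          as.integer(st[ch] != st[p])
        }
      }
    }
    tot <- rowSums(costs)
    mpr <- costs[tot == min(tot), , drop = FALSE]
    mins <- mins + apply(mpr, 2, min) * m$weights[j]
  }
  as.integer(mins)
}

clade_row <- function(m, clade) {
  parsmix:::clade_support_row(m, clade, partitions = names(m$partitions),
                              n_replicates = 8, seed = 5)
}
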