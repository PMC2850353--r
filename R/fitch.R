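#' Fitch parsimony length of a tree
#'
#' Minimum number of character-state changes required by `tree` for the
#' unordered, weighted characters of `m`, summed over characters. Missing
#' cells never force steps. Multi-state cells are handled in one of two modes:
#' in `"uncertainty"` mode (standard Fitch state sets) any one member of the
#' set can satisfy the cell; in `"polymorphism"` mode the reconstruction must
#' account for every member of the set, with extra steps charged via a
#' Sankoff-style dynamic program over state subsets (the cost of moving
#' between subsets A and B is `max(|A\\B|, |B\\A|)`, which reduces to ordinary
#' Fitch counting when all cells are singletons).
#'
#' @param tree a `phylo`; leaves must be a subset of the matrix taxa (the
#'   matrix is restricted to the tree's leaves).
#' @param m a [char_matrix()].
#' @param mode `"uncertainty"` (default) or `"polymorphism"`.
#' @return an object of class `length_report`: list with `total_steps`,
#'   `per_partition_steps` (named integer) and `per_character_steps`.
#'   Use [tidy()][generics::tidy] for a tibble.
#' @export
fitch_length <- function(tree, m, mode = c("uncertainty", "polymorphism")) {
  mode <- match.arg(mode)
  tree <- prepare_tree(tree, m)
  if (length(tree$tip.label) < n_taxa(m)) {
    m <- restrict_matrix(m, taxa = tree$tip.label)
  }
  if (!is_binary_unrooted(tree)) {
    abort("fitch_length() expects a fully resolved (binary) unrooted tree.")
  }
  perm <- match(tree$tip.label, m$taxa)
  nchs <- n_char(m)
  per_char <- integer(nchs)

  poly <- logical(nchs)
  if (mode == "polymorphism") {
    pop <- matrix(popcount32(m$masks), nrow = n_taxa(m))
    poly <- apply(pop > 1L, 2L, any)
  }

  std <- which(!poly)
  if (length(std)) {
    masks <- fitch_masks(m, std)[perm, , drop = FALSE]
    per_char[std] <- fitch_per_pattern_cpp(tree$edge, length(tree$tip.label),
                                           masks)
  }
  for (j in which(poly)) {
    per_char[j] <- poly_char_length(tree, m$masks[perm, j],
                                    length(m$symbols[[j]]))
  }
  per_char <- per_char * m$weights

  per_part <- vapply(m$partitions, function(idx) sum(per_char[idx]), numeric(1))
  structure(
    list(
      total_steps = sum(per_char),
      per_partition_steps = per_part,
      per_character_steps = per_char,
      mode = mode
    ),
    class = "length_report"
  )
}

#' @export
print.length_report <- function(x, ...) {
  cat("<length_report> total steps: ", x$total_steps, " (", x$mode,
      " mode)\n", sep = "")
  cat("  per partition: ",
      paste0(names(x$per_partition_steps), "=", x$per_partition_steps,
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fitch length restricted to one partition
#'
#' @inheritParams fitch_length
#' @param partition a partition name of `m` (or several, summed).
#' @return integer steps.
#' @export
partition_length <- function(tree, m, partition,
                             mode = c("uncertainty", "polymorphism")) {
  mode <- match.arg(mode)
  idx <- partition_indices(m, partition)
  rep <- fitch_length(tree, m, mode = mode)
  sum(rep$per_character_steps[idx])
}

# number of set bits for each element of an integer vector/matrix
popcount32 <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x != 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# Sankoff DP over state subsets for one character with polymorphic cells.
# Observed cells must be reconstructed as exactly their state set; ancestral
# nodes range over all non-empty subsets; d(A,B) = max(|A\B|, |B\A|).
poly_char_length <- function(tree, masks_col, k) {
  nsub <- bitwShiftL(1L, k) - 1L
  subs <- seq_len(nsub)
  pc <- popcount32(subs)
  D <- outer(subs, subs, function(a, b) {
    pmax(popcount32(bitwAnd(a, bitwNot(b))), popcount32(bitwAnd(b, bitwNot(a))))
  })
  n <- length(tree$tip.label)
  edge <- tree$edge
  nnode <- max(edge)
  INF <- 1e9
  cost <- matrix(0, nnode, nsub)
  for (i in seq_len(n)) {
    if (masks_col[i] != 0L) {
      cost[i, ] <- INF
      cost[i, masks_col[i]] <- 0
    }
  }
  # postorder over edges, accumulating child contributions into parents
  tre2 <- stats::reorder(tree, "postorder")
  for (r in seq_len(nrow(tre2$edge))) {
    p <- tre2$edge[r, 1]
    ch <- tre2$edge[r, 2]
    add <- apply(D + rep(cost[ch, ], each = nsub), 1L, min)
    cost[p, ] <- cost[p, ] + add
  }
  root <- setdiff(tre2$edge[, 1], tre2$edge[, 2])[1]
  min(cost[root, ])
}

#' Exhaustive minimum-steps oracle for tiny trees
#'
#' Computes the minimum number of changes by enumerating every assignment of
#' single states to the internal nodes (uncertainty handling of multi-state
#' cells: a leaf is satisfied by any member of its set; missing cells are
#' free). Intended as an independent check of [fitch_length()]; refuses
#' instances with more than 8 leaves.
#'
#' @inheritParams fitch_length
#' @return integer steps.
#' @export
brute_force_length <- function(tree, m) {
  tree <- prepare_tree(tree, m)
  if (length(tree$tip.label) < n_taxa(m)) {
    m <- restrict_matrix(m, taxa = tree$tip.label)
  }
  n <- length(tree$tip.label)
  if (n > 8L) {
    abort("brute_force_length() enumerates internal assignments and is limited to 8 leaves.")
  }
  perm <- match(tree$tip.label, m$taxa)
  edge <- tree$edge
  internal <- sort(unique(edge[, 1]))
  total <- 0L
  for (j in seq_len(n_char(m))) {
    k <- length(m$symbols[[j]])
    masks <- fitch_masks(m, j)[perm, 1]
    if (k == 1L) next
    grids <- rep(list(seq_len(k)), length(internal))
    assign <- as.matrix(expand.grid(grids))
    best <- Inf
    for (r in seq_len(nrow(assign))) {
      states <- integer(max(edge))
      states[internal] <- assign[r, ]
      steps <- 0L
      for (e in seq_len(nrow(edge))) {
        p <- edge[e, 1]
        ch <- edge[e, 2]
        sp <- bitwShiftL(1L, states[p] - 1L)
        if (ch <= n) {
          if (bitwAnd(sp, masks[ch]) == 0L) steps <- steps + 1L
        } else {
          if (states[ch] != states[p]) steps <- steps + 1L
        }
      }
      if (steps < best) best <- steps
      if (best == 0L) break
    }
    total <- total + best * m$weights[j]
  }
  total
}

#' ACCTRAN branch step counts and per-branch minima
#'
#' Optimizes every character on a fully resolved tree rooted at a designated
#' outgroup taxon, placing ambiguous changes as close to the root as possible
#' (accelerated transformation), and reports the number of changes assigned to
#' each branch together with the minimum number of changes that branch must
#' carry in *any* most-parsimonious reconstruction (the quantity behind the
#' MINBRLEN collapse rule). Ties among equally accelerated states are broken
#' deterministically by state order.
#'
#' @param tree an unrooted binary `phylo`.
#' @param m a [char_matrix()].
#' @param outgroup taxon label used to orient the optimization; default: the
#'   tree's first tip.
#' @return a tibble with one row per branch: `parent`, `child` (ape node ids),
#'   `clade` (tip labels below the branch, away from the outgroup),
#'   `acctran_steps` and `min_steps`. Attribute `total_steps` carries the tree
#'   length; `sum(acctran_steps) == total_steps` always.
#' @export
branch_steps <- function(tree, m, outgroup = NULL) {
  tree <- prepare_tree(tree, m)
  if (length(tree$tip.label) < n_taxa(m)) {
    m <- restrict_matrix(m, taxa = tree$tip.label)
  }
  if (!is_binary_unrooted(tree)) {
    abort("branch_steps() requires a fully resolved tree; resolve or collapse first.")
  }
  outgroup <- outgroup %||% tree$tip.label[1]
  og <- match(outgroup, tree$tip.label)
  if (is.na(og)) abort(paste0("outgroup '", outgroup, "' is not a tree tip."))

  perm <- match(tree$tip.label, m$taxa)
  cmp <- compress_patterns(m, perm)
  n <- length(tree$tip.label)
  acc <- acctran_cpp(tree$edge, n, cmp$masks, cmp$weights, og)
  mins <- branch_min_cpp(tree$edge, n, cmp$masks, cmp$weights)

  clades <- edge_clades(tree, og)
  tibble(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    clade = clades,
    acctran_steps = as.integer(acc$steps),
    min_steps = as.integer(mins)
  ) -> out
  attr(out, "total_steps") <- acc$total
  out
}

# unique site patterns with aggregated weights (Fitch-masked)
compress_patterns <- function(m, perm = seq_len(n_taxa(m)),
                              chars = seq_len(n_char(m))) {
  masks <- fitch_masks(m, chars)[perm, , drop = FALSE]
  key <- apply(masks, 2L, paste0, collapse = ",")
  grp <- match(key, unique(key))
  w <- vapply(split(m$weights[chars], grp), sum, numeric(1))
  keep <- !duplicated(grp)
  list(masks = masks[, keep, drop = FALSE], weights = as.integer(w))
}

# tip labels below each edge when the tree is rooted at tip `og`
edge_clades <- function(tree, og) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  adj <- vector("list", max(edge))
  for (e in seq_len(nrow(edge))) {
    adj[[edge[e, 1]]] <- c(adj[[edge[e, 1]]], edge[e, 2])
    adj[[edge[e, 2]]] <- c(adj[[edge[e, 2]]], edge[e, 1])
  }
  parent <- integer(max(edge))
  ord <- integer(0)
  stack <- og
  parent[og] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (w in adj[[v]]) {
      if (parent[v] != w) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  below <- vector("list", max(edge))
  for (v in rev(ord)) {
    if (v <= n) {
      below[[v]] <- tree$tip.label[v]
    }
    if (parent[v] > 0L) {
      below[[parent[v]]] <- c(below[[parent[v]]], below[[v]])
    }
  }
  vapply(seq_len(nrow(edge)), function(e) {
    a <- edge[e, 1]
    b <- edge[e, 2]
    child <- if (parent[b] == a) b else a
    paste(sort(below[[child]]), collapse = ";")
  }, character(1))
}

#' Count parsimony-informative characters
#'
#' A character is parsimony informative when at least two of its states each
#' occur in at least two taxa; only unambiguous singleton cells count as
#' occurrences (missing and polymorphic cells contribute nothing).
#'
#' @param m a [char_matrix()].
#' @param partition partition name(s), or `NULL` for the whole matrix.
#' @return integer count.
#' @export
count_parsimony_informative <- function(m, partition = NULL) {
  idx <- if (is.null(partition)) seq_len(n_char(m)) else partition_indices(m, partition)
  sum(vapply(idx, function(j) char_is_informative(m$masks[, j]), logical(1)))
}

char_is_informative <- function(masks_col) {
  single <- masks_col[popcount32(masks_col) == 1L]
  if (length(single) < 4L) return(FALSE)
  counts <- table(single)
  sum(counts >= 2L) >= 2L
}

#' Per-partition matrix statistics
#'
#' @param m a [char_matrix()].
#' @return a tibble with one row per partition: character count, datatype
#'   breakdown, counts of variable and parsimony-informative characters, and
#'   the fraction of missing cells.
#' @export
matrix_stats <- function(m) {
  purrr::map_dfr(names(m$partitions), function(p) {
    idx <- m$partitions[[p]]
    sub <- m$masks[, idx, drop = FALSE]
    pop <- matrix(popcount32(sub), nrow = n_taxa(m))
    variable <- vapply(seq_along(idx), function(jj) {
      s <- sub[, jj][pop[, jj] == 1L]
      length(unique(s)) > 1L
    }, logical(1))
    tibble(
      partition = p,
      n_char = length(idx),
      datatype = paste(unique(m$datatype[idx]), collapse = "+"),
      n_variable = sum(variable),
      n_informative = count_parsimony_informative(m, p),
      missing_frac = mean(sub == 0L)
    )
  })
}
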