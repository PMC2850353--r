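#' Clade constraint for tree search
#'
#' A positive constraint retains only trees that display the clade; a converse
#' constraint retains only trees that do *not* (the form used for Bremer
#' support).
#'
#' @param taxa character vector of taxon labels forming the clade.
#' @param converse `TRUE` to forbid the clade instead of enforcing it.
#' @return an object of class `clade_constraint`.
#' @export
clade_constraint <- function(taxa, converse = FALSE) {
  structure(list(taxa = unique(as.character(taxa)), converse = converse),
            class = "clade_constraint")
}

#' @export
print.clade_constraint <- function(x, ...) {
  cat("<clade_constraint> ", if (x$converse) "converse (forbid)" else "positive (enforce)",
      ": {", paste(x$taxa, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

check_constraint <- function(constraint, m) {
  if (is.null(constraint)) return(NULL)
  if (!inherits(constraint, "clade_constraint")) {
    abort("`constraint` must be built with clade_constraint().")
  }
  bad <- setdiff(constraint$taxa, m$taxa)
  if (length(bad)) {
    abort(paste0("constraint taxa not in matrix: ", paste(bad, collapse = ", ")))
  }
  k <- length(constraint$taxa)
  if (k < 2L || k > n_taxa(m) - 2L) {
    abort("constraint clade must contain 2 to n-2 of the matrix taxa.")
  }
  constraint
}

#' Heuristic maximum-parsimony tree search
#'
#' Random (or as-is) stepwise addition followed by TBR branch swapping,
#' repeated over `n_replicates` starting trees. All equally most-parsimonious
#' trees found across replicates are pooled, collapsed under the MINBRLEN rule
#' (branches with no unambiguous change removed) and deduplicated by
#' bipartition set. An optional clade constraint is honoured during swapping:
#' candidate trees violating it are discarded at generation time.
#'
#' @param m a [char_matrix()] with at least 4 (and at most 64) taxa.
#' @param n_replicates number of addition-sequence replicates.
#' @param addition `"random"` (seeded taxon permutation per replicate) or
#'   `"as-is"` (matrix order, one deterministic replicate is enough).
#' @param seed integer seed; identical seed and inputs give identical results.
#' @param constraint optional [clade_constraint()].
#' @param improvement TBR move acceptance: `"best"` evaluates the full
#'   neighborhood and jumps to its best tree; `"first"` takes the first strict
#'   improvement.
#' @param max_trees cap on the equally-best tree buffer per replicate
#'   (`NULL` = unbounded); hitting the cap sets the `capped` flag.
#' @param collapse apply MINBRLEN collapsing to the reported trees.
#' @return an object of class `mp_search`: `best_length`, `trees` (collapsed,
#'   deduplicated `multiPhylo`), `binary_trees` (pre-collapse resolutions),
#'   `replicates_run`, `seed`, `capped`.
#' @export
heuristic_search <- function(m, n_replicates = 10, addition = c("random", "as-is"),
                             seed = 1L, constraint = NULL,
                             improvement = c("best", "first"),
                             max_trees = NULL, collapse = TRUE) {
  addition <- match.arg(addition)
  improvement <- match.arg(improvement)
  constraint <- check_constraint(constraint, m)
  n <- n_taxa(m)
  if (n > 64L) abort("searches support at most 64 taxa.")
  if (n < 4L) {
    return(trivial_search_result(m, seed,
                                 note = "fewer than 4 taxa: topology is unique"))
  }
  cmp <- compress_patterns(m)
  clade_tips <- if (!is.null(constraint)) match(constraint$taxa, m$taxa) else integer(0)
  converse <- !is.null(constraint) && constraint$converse
  cap <- if (is.null(max_trees)) .Machine$integer.max else as.integer(max_trees)

  best <- Inf
  pool_edges <- list()
  pool_keys <- character(0)
  capped <- FALSE

  withr::with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      ord <- addition_order(m, addition, clade_tips, converse)
      st <- stepwise_addition_cpp(n, cmp$masks, cmp$weights, ord,
                                  clade_tips, converse)
      res <- tbr_search_cpp(st$edge, n, cmp$masks, cmp$weights,
                            clade_tips, converse, improvement == "first", cap)
      if (res$capped) capped <- TRUE
      if (res$best_length < best) {
        best <- res$best_length
        pool_edges <- list()
        pool_keys <- character(0)
      }
      if (res$best_length == best) {
        for (e in res$trees) {
          k <- tree_key_cpp(e, n)
          if (!k %in% pool_keys) {
            pool_keys <- c(pool_keys, k)
            pool_edges <- c(pool_edges, list(e))
          }
        }
      }
    }
  })

  finalize_search(m, best, pool_edges, n_replicates, seed, collapse,
                  capped = capped, method = "heuristic")
}

addition_order <- function(m, addition, clade_tips, converse) {
  n <- n_taxa(m)
  if (addition == "as-is") {
    ord <- seq_len(n)
  } else {
    ord <- sample.int(n)
  }
  if (length(clade_tips) && !converse) {
    # positive constraint: build the clade subtree first so every partial
    # tree can still display the clade
    inside <- ord[ord %in% clade_tips]
    ord <- c(inside, ord[!ord %in% clade_tips])
  }
  ord
}

trivial_search_result <- function(m, seed, note) {
  n <- n_taxa(m)
  txt <- if (n == 2L) {
    paste0("(", m$taxa[1], ",", m$taxa[2], ");")
  } else {
    paste0("(", paste(m$taxa, collapse = ","), ");")
  }
  tree <- ape::read.tree(text = txt)
  len <- if (n == 2L) {
    sum(m$weights[vapply(seq_len(n_char(m)), function(j) {
      a <- m$masks[1, j]
      b <- m$masks[2, j]
      a != 0L && b != 0L && bitwAnd(a, b) == 0L
    }, logical(1))])
  } else {
    0L
  }
  if (n == 3L) {
    cmp <- compress_patterns(m)
    len <- sum(fitch_per_pattern_cpp(tree_edge_3taxon(), 3L, cmp$masks) *
                 cmp$weights)
  }
  trees <- c(tree)
  class(trees) <- "multiPhylo"
  structure(
    list(best_length = len, trees = trees, binary_trees = trees,
         replicates_run = 0L, seed = seed, capped = FALSE,
         method = "trivial", note = note),
    class = "mp_search"
  )
}

tree_edge_3taxon <- function() {
  matrix(c(4L, 4L, 4L, 1L, 2L, 3L), ncol = 2L)
}

finalize_search <- function(m, best, pool_edges, replicates, seed, collapse,
                            capped, method) {
  binary <- lapply(pool_edges, phylo_from_edge, labels = m$taxa)
  if (collapse) {
    collapsed <- lapply(binary, collapse_minbrlen, m = m)
  } else {
    collapsed <- binary
  }
  keys <- vapply(collapsed, topology_key, character(1))
  keep <- !duplicated(keys)
  trees <- collapsed[keep]
  class(trees) <- "multiPhylo"
  class(binary) <- "multiPhylo"
  structure(
    list(best_length = as.integer(best), trees = trees, binary_trees = binary,
         replicates_run = replicates, seed = seed, capped = capped,
         method = method),
    class = "mp_search"
  )
}

#' @export
print.mp_search <- function(x, ...) {
  cat("<mp_search> ", x$method, " search: best length ", x$best_length, ", ",
      length(x$trees), " optimal tree(s) after collapse", sep = "")
  if (x$capped) cat(" [tree buffer capped]")
  cat("\n")
  invisible(x)
}

#' Exhaustive maximum-parsimony search
#'
#' Scores every unrooted binary topology (at most 9 taxa, i.e. 135,135
#' topologies) and returns the global optimum set, collapsed and
#' deduplicated exactly as [heuristic_search()] does.
#'
#' @inheritParams heuristic_search
#' @return an `mp_search` object; `$n_scored` records how many topologies
#'   were visited before pruning.
#' @export
exhaustive_search <- function(m, collapse = TRUE) {
  n <- n_taxa(m)
  if (n > 9L) {
    ntopo <- prod(seq(3, 2 * n - 5, by = 2))
    abort(paste0("exhaustive search over ", n, " taxa would score ",
                 format(ntopo, big.mark = ","),
                 " topologies; limit is 9 taxa (135,135)."))
  }
  if (n < 4L) {
    return(trivial_search_result(m, seed = NA_integer_,
                                 note = "fewer than 4 taxa: topology is unique"))
  }
  cmp <- compress_patterns(m)
  res <- exhaustive_search_cpp(n, cmp$masks, cmp$weights)
  out <- finalize_search(m, res$best_length, res$trees, NA_integer_,
                         NA_integer_, collapse, capped = FALSE,
                         method = "exhaustive")
  out$n_scored <- res$n_scored
  out
}

#' Strict or majority-rule consensus
#'
#' @param trees a `multiPhylo` (or list of `phylo`) on identical leaf sets.
#' @param method `"strict"` keeps clades present in every tree; `"majority"`
#'   keeps clades whose frequency exceeds `cutoff` percent.
#' @param cutoff majority threshold in percent (default 50).
#' @return an object of class `consensus_tree`: the consensus `phylo`, the
#'   method, and a tibble of clade frequencies across the input trees.
#' @export
consensus_tree <- function(trees, method = c("strict", "majority"), cutoff = 50) {
  method <- match.arg(method)
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees <- unclass(trees)
  labs <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(labs)[-1]) {
    if (!identical(labs[[i]], labs[[1]])) {
      diff <- c(setdiff(labs[[i]], labs[[1]]), setdiff(labs[[1]], labs[[i]]))
      abort(paste0("trees have mismatched leaf sets; differing taxa: ",
                   paste(diff, collapse = ", ")))
    }
  }
  taxa <- labs[[1]]
  keysets <- lapply(trees, tree_split_keys, taxa = taxa)
  counts <- table(unlist(keysets))
  freq <- as.numeric(counts) / length(trees)
  names(freq) <- names(counts)

  keep <- if (method == "strict") {
    names(counts)[as.integer(counts) == length(trees)]
  } else {
    names(freq)[freq > cutoff / 100]
  }
  tree <- tree_from_split_keys(keep, taxa)
  structure(
    list(
      tree = tree, method = method,
      cutoff = if (method == "majority") cutoff else 100,
      clade_freq = tibble(
        clade = names(freq),
        frequency = as.numeric(freq),
        in_consensus = names(freq) %in% keep
      )
    ),
    class = "consensus_tree"
  )
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("<consensus_tree> ", x$method,
      if (x$method == "majority") paste0(" (>", x$cutoff, "%)"),
      ": ", x$tree$Nnode, " internal node(s)\n", sep = "")
  invisible(x)
}

# Build a (multifurcating, unrooted) tree displaying exactly the given
# compatible splits. Splits come from a consensus filter, so compatibility
# holds; construction is by nesting clades.
tree_from_split_keys <- function(keys, taxa) {
  clades <- lapply(keys, function(k) strsplit(k, ";", fixed = TRUE)[[1]])
  # order big to small so children nest inside parents
  clades <- clades[order(-lengths(clades))]
  newick_of <- function(members, sub) {
    # sub: clades fully inside members, ordered big->small
    parts <- list()
    used <- character(0)
    while (length(sub)) {
      top <- sub[[1]]
      inner <- Filter(function(cl) all(cl %in% top), sub[-1])
      parts <- c(parts, list(newick_of(top, inner)))
      used <- c(used, top)
      sub <- Filter(function(cl) !all(cl %in% top), sub[-1])
    }
    loose <- setdiff(members, used)
    paste0("(", paste(c(loose, unlist(parts)), collapse = ","), ")")
  }
  txt <- paste0(newick_of(taxa, clades), ";")
  ape::read.tree(text = txt)
}

#' Nonparametric bootstrap clade support
#'
#' Resamples characters with replacement (each resampled character keeps its
#' weight), runs one addition-sequence-plus-TBR search per pseudoreplicate,
#' and tallies clade frequencies. By default each pseudoreplicate contributes
#' the clades of the strict consensus of its equally best trees; with
#' `tally = "all"`, every optimal tree contributes equally (weight 1/k).
#'
#' @inheritParams heuristic_search
#' @param n_pseudoreplicates number of bootstrap pseudoreplicates.
#' @param addition `"simple"` (taxa added in matrix order, PAUP*'s
#'   ADDSEQ=SIMPLE analogue) or `"random"`.
#' @param tally `"consensus"` or `"all"`, see above.
#' @return a tibble with one row per clade observed in any pseudoreplicate:
#'   `clade` (canonical taxon-set key), `support` (percent), `reported`
#'   (support at or above 50, the conventional reporting floor).
#' @export
bootstrap_support <- function(m, n_pseudoreplicates = 100,
                              seed = 1L, addition = c("simple", "random"),
                              tally = c("consensus", "all"),
                              max_trees = 100) {
  addition <- match.arg(addition)
  tally <- match.arg(tally)
  if (n_pseudoreplicates < 1L) abort("need at least one pseudoreplicate.")
  n <- n_taxa(m)
  if (n < 4L) abort("bootstrap needs at least 4 taxa.")
  taxa <- sort(m$taxa)
  acc <- numeric(0)

  withr::with_seed(seed, {
    for (b in seq_len(n_pseudoreplicates)) {
      idx <- sample.int(n_char(m), n_char(m), replace = TRUE)
      mb <- subset_chars(m, idx)
      ord <- if (addition == "simple") seq_len(n) else sample.int(n)
      cmp <- compress_patterns(mb)
      st <- stepwise_addition_cpp(n, cmp$masks, cmp$weights, ord,
                                  integer(0), FALSE)
      res <- tbr_search_cpp(st$edge, n, cmp$masks, cmp$weights, integer(0),
                            FALSE, FALSE, as.integer(max_trees))
      trees <- lapply(res$trees, phylo_from_edge, labels = m$taxa)
      if (tally == "consensus") {
        keys <- if (length(trees) == 1L) {
          tree_split_keys(trees[[1]], taxa)
        } else {
          Reduce(intersect, lapply(trees, tree_split_keys, taxa = taxa))
        }
        w <- stats::setNames(rep(1, length(keys)), keys)
      } else {
        keys <- unlist(lapply(trees, tree_split_keys, taxa = taxa))
        w <- tapply(rep(1 / length(trees), length(keys)), keys, sum)
        w <- stats::setNames(as.numeric(w), names(w))
      }
      for (k in names(w)) {
        acc[k] <- (if (k %in% names(acc)) acc[[k]] else 0) + w[[k]]
      }
    }
  })

  out <- tibble(
    clade = names(acc),
    support = 100 * unname(acc) / n_pseudoreplicates
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$support))
  out$reported <- out$support >= 50
  attr(out, "n_pseudoreplicates") <- n_pseudoreplicates
  out
}

subset_chars <- function(m, idx) {
  new_char_matrix(m$taxa, m$masks[, idx, drop = FALSE], m$symbols[idx],
                  m$datatype[idx], m$weights[idx],
                  list(all = seq_along(idx)))
}
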