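#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a tree-length report
#'
#' @param x a [fitch_length()] result.
#' @param ... unused.
#' @return tibble with one row per partition: `partition`, `steps`.
#' @export
tidy.length_report <- function(x, ...) {
  tibble(partition = names(x$per_partition_steps),
         steps = as.integer(x$per_partition_steps))
}

#' @rdname tidy.length_report
#' @export
glance.length_report <- function(x, ...) {
  tibble(total_steps = x$total_steps, mode = x$mode,
         n_characters = length(x$per_character_steps))
}

#' Tidy a parsimony search result
#'
#' @param x an `mp_search` from [heuristic_search()] or [exhaustive_search()].
#' @param ... unused.
#' @return `tidy()`: one row per optimal tree with its newick string and
#'   resolution; `glance()`: a one-row summary.
#' @export
tidy.mp_search <- function(x, ...) {
  tibble(
    tree = seq_along(x$trees),
    newick = vapply(x$trees, function(t) ape::write.tree(t), character(1)),
    n_internal_branches = vapply(x$trees, function(t) {
      sum(t$edge[, 2] > length(t$tip.label))
    }, numeric(1))
  )
}

#' @rdname tidy.mp_search
#' @export
glance.mp_search <- function(x, ...) {
  tibble(
    best_length = x$best_length,
    n_trees = length(x$trees),
    replicates_run = x$replicates_run,
    seed = x$seed,
    capped = x$capped,
    method = x$method
  )
}

#' Tidy a consensus tree
#'
#' @param x a [consensus_tree()] result.
#' @param ... unused.
#' @return the clade-frequency tibble (`clade`, `frequency`, `in_consensus`).
#' @export
tidy.consensus_tree <- function(x, ...) {
  x$clade_freq
}

#' Tidy a root survey
#'
#' @param x a [survey_root()] result.
#' @param ... unused.
#' @return `tidy()`: per-branch attachment tallies; `glance()`: totals.
#' @export
tidy.root_survey <- function(x, ...) {
  x$counts
}

#' @rdname tidy.root_survey
#' @export
glance.root_survey <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_resolved = x$n_total - x$unresolved_count,
    unresolved_count = x$unresolved_count,
    n_branches_hit = nrow(x$counts),
    modal_count = if (nrow(x$counts)) max(x$counts$count) else 0L
  )
}
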