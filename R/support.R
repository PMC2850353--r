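#' Bremer (decay) support for a clade
#'
#' Extra steps required by the best trees *lacking* the clade, relative to the
#' unconstrained optimum: a converse-constrained heuristic search is run and
#' its best length compared with the unconstrained best length.
#'
#' @param m a [char_matrix()].
#' @param clade character vector of taxon labels (proper subset, size 2..n-2).
#' @param n_replicates,seed search settings passed to [heuristic_search()]
#'   (100 random-addition replicates is the conventional setting for support
#'   calculations; the default here is lighter).
#' @param baseline optional precomputed unconstrained `mp_search` for `m`,
#'   reused across clades.
#' @return one-row tibble: `comb` (unconstrained best length), `comb_wo`
#'   (best length without the clade), `bs` (Bremer support).
#' @export
bremer_support <- function(m, clade, n_replicates = 20, seed = 1L,
                           baseline = NULL) {
  row <- clade_support_row(m, clade, partitions = character(0),
                           n_replicates = n_replicates, seed = seed,
                           baseline = baseline)
  row[c("comb", "comb_wo", "bs")]
}

#' Partitioned branch support (PBS)
#'
#' A partition's contribution to a clade's Bremer support: the minimum length
#' of the partition's characters across the shortest combined-data trees
#' lacking the clade, minus its minimum across the shortest combined trees
#' containing the clade. Negative values mean the partition conflicts with
#' the clade.
#'
#' @inheritParams bremer_support
#' @param partition partition name.
#' @return numeric PBS (may be negative).
#' @export
partitioned_branch_support <- function(m, clade, partition, n_replicates = 20,
                                       seed = 1L, baseline = NULL) {
  row <- clade_support_row(m, clade, partitions = partition,
                           n_replicates = n_replicates, seed = seed,
                           baseline = baseline)
  row[[paste0(partition, "_bs")]]
}

#' Hidden branch support (HBS)
#'
#' Support that emerges only from interaction between partitions: the combined
#' Bremer support minus the sum of the partitioned branch supports.
#'
#' @param bs combined-data Bremer support.
#' @param pbs numeric vector of per-partition branch supports (no missing
#'   values allowed).
#' @return numeric HBS.
#' @export
hidden_branch_support <- function(bs, pbs) {
  if (length(pbs) == 0L || anyNA(pbs)) {
    abort("hidden_branch_support() needs a PBS value for every partition.")
  }
  bs - sum(pbs)
}

# One clade's full support-table row. The "with-clade" tree set is the subset
# of optimal trees containing the clade (falling back to a positive-constrained
# search when no optimal tree does); the "without" set comes from a
# converse-constrained search. Per-partition lengths are minimized
# independently over each tree set unless joint_tree = TRUE, in which case a
# single tree minimizing the combined length breaks ties by partition order.
clade_support_row <- function(m, clade, partitions, n_replicates, seed,
                              baseline = NULL, joint_tree = FALSE) {
  if (is.null(baseline)) {
    baseline <- heuristic_search(m, n_replicates = n_replicates, seed = seed)
  }
  L <- baseline$best_length

  with_trees <- Filter(function(t) has_clade(t, clade), baseline$binary_trees)
  constrained_with <- FALSE
  if (length(with_trees) == 0L) {
    pos <- heuristic_search(m, n_replicates = n_replicates, seed = seed,
                            constraint = clade_constraint(clade))
    with_trees <- pos$binary_trees
    constrained_with <- TRUE
  }
  wo <- heuristic_search(m, n_replicates = n_replicates, seed = seed,
                         constraint = clade_constraint(clade, converse = TRUE))
  wo_trees <- wo$binary_trees

  with_len <- min(vapply(with_trees, function(t) {
    fitch_length(t, m)$total_steps
  }, numeric(1)))
  out <- tibble(
    comb = L,
    comb_with = with_len,
    comb_wo = wo$best_length,
    bs = wo$best_length - L,
    constrained_with = constrained_with
  )
  if (length(partitions)) {
    plen <- function(trees) {
      sapply(partitions, function(p) {
        vapply(trees, partition_length, numeric(1), m = m, partition = p)
      })
    }
    pw_mat <- matrix(plen(with_trees), ncol = length(partitions),
                     dimnames = list(NULL, partitions))
    pwo_mat <- matrix(plen(wo_trees), ncol = length(partitions),
                      dimnames = list(NULL, partitions))
    if (joint_tree) {
      iw <- do.call(order, as.data.frame(pw_mat))[1]
      iwo <- do.call(order, as.data.frame(pwo_mat))[1]
      pw <- pw_mat[iw, ]
      pwo <- pwo_mat[iwo, ]
    } else {
      pw <- apply(pw_mat, 2L, min)
      pwo <- apply(pwo_mat, 2L, min)
    }
    for (p in partitions) {
      out[[p]] <- pw[[p]]
      out[[paste0(p, "_wo")]] <- pwo[[p]]
      out[[paste0(p, "_bs")]] <- pwo[[p]] - pw[[p]]
    }
  }
  out
}

#' Branch-support table across data partitions
#'
#' For each named clade, computes the combined-data Bremer support, the
#' partitioned branch support of every partition, and the hidden branch
#' support, mirroring the usual published column layout
#' (combined / combined-without / BS, then per partition, then HBS).
#'
#' @inheritParams bremer_support
#' @param clades named list of taxon-label vectors, one entry per clade.
#' @param partitions partition names; default: all partitions of `m`.
#' @return a `support_table` tibble: one row per clade with columns `clade`,
#'   `comb`, `comb_wo`, `bs`, then `<p>`, `<p>_wo`, `<p>_bs` for each
#'   partition `p`, then `hbs`.
#' @export
build_support_table <- function(m, clades, partitions = names(m$partitions),
                                n_replicates = 20, seed = 1L,
                                baseline = NULL) {
  if (is.null(names(clades)) || anyDuplicated(names(clades))) {
    abort("`clades` must be a uniquely named list of taxon vectors.")
  }
  if (is.null(baseline)) {
    baseline <- heuristic_search(m, n_replicates = n_replicates, seed = seed)
  }
  rows <- purrr::map_dfr(names(clades), function(lab) {
    row <- clade_support_row(m, clades[[lab]], partitions,
                             n_replicates = n_replicates, seed = seed,
                             baseline = baseline)
    pbs <- vapply(partitions, function(p) row[[paste0(p, "_bs")]], numeric(1))
    dplyr::bind_cols(tibble(clade = lab), row,
                     tibble(hbs = hidden_branch_support(row$bs, pbs)))
  })
  class(rows) <- c("support_table", class(rows))
  rows
}

#' Write a support table as TSV
#'
#' @param tbl a [build_support_table()] result.
#' @param file output path.
#' @return the input, invisibly.
#' @export
write_support_table <- function(tbl, file) {
  utils::write.table(as.data.frame(tbl), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tbl)
}

#' Published branch-support values for the golden-mole combined analysis
#'
#' The published partitioned branch-support table for Chrysochloridae (golden
#' moles): 23 clades scored on a combined matrix of nuclear GHR sequence,
#' morphology and indel partitions, with combined and per-partition tree
#' lengths with and without each clade, the derived Bremer support (BS),
#' partitioned branch support (PBS) and hidden branch support (HBS). Shipped
#' as a plain-text fixture to exercise the HBS arithmetic
#' (`hbs == bs - (ghr_bs + morph_bs + indel_bs)`) independently of any search.
#'
#' @return a tibble with columns `node`, `comb`, `comb_wo`, `comb_bs`, `ghr`,
#'   `ghr_wo`, `ghr_bs`, `morph`, `morph_wo`, `morph_bs`, `indel`, `indel_wo`,
#'   `indel_bs`, `hbs`.
#' @export
chrysochloridae_support_table <- function() {
  path <- system.file("extdata", "chrysochloridae_branch_support.tsv",
                      package = "parsmix", mustWork = TRUE)
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
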