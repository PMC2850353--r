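#' Specification for random artificial outgroup taxa
#'
#' Describes the composition of artificial taxa used by the random-outgroup
#' rooting diagnostic: i.i.d. nucleotides drawn from fixed base frequencies,
#' followed by random binary morphological and indel characters. The defaults
#' are the conventional configuration for a GHR-plus-morphology matrix: 913
#' nucleotides at frequencies A 0.28, C 0.27, G 0.22, T 0.23, then 145 binary
#' morphological and 8 binary indel characters.
#'
#' @param n_nucleotides number of DNA sites.
#' @param base_frequencies named numeric simplex over A, C, G, T.
#' @param n_morphology number of random binary morphological characters.
#' @param n_indel number of random binary indel characters.
#' @param binary_p probability of state "1" for the binary characters.
#' @return an object of class `outgroup_spec`.
#' @export
random_outgroup_spec <- function(n_nucleotides = 913,
                                 base_frequencies = c(A = 0.28, C = 0.27,
                                                      G = 0.22, T = 0.23),
                                 n_morphology = 145, n_indel = 8,
                                 binary_p = 0.5) {
  if (abs(sum(base_frequencies) - 1) > 1e-9) {
    abort("base frequencies must sum to 1.")
  }
  if (!setequal(names(base_frequencies), DNA_SYMBOLS)) {
    abort("base frequencies must be named A, C, G, T.")
  }
  if (n_nucleotides < 0 || n_morphology < 0 || n_indel < 0) {
    abort("character counts must be non-negative.")
  }
  structure(
    list(n_nucleotides = as.integer(n_nucleotides),
         base_frequencies = base_frequencies[DNA_SYMBOLS],
         n_morphology = as.integer(n_morphology),
         n_indel = as.integer(n_indel),
         binary_p = binary_p),
    class = "outgroup_spec"
  )
}

#' Generate one random artificial outgroup row
#'
#' Draws an artificial taxon per an [random_outgroup_spec()]: nucleotides
#' i.i.d. from the base frequencies, binary characters i.i.d. Bernoulli. When
#' a target matrix is supplied the row is laid out against its characters (DNA
#' characters receive nucleotides in order, all other characters binary
#' states) and the spec's counts must match the matrix's partition sizes
#' unless `override = TRUE`.
#'
#' @param spec an [random_outgroup_spec()].
#' @param m optional target [char_matrix()].
#' @param seed integer seed (deterministic output).
#' @param override allow spec counts that disagree with the matrix layout (the
#'   matrix's own layout wins).
#' @return character vector of cell strings (one per character of `m`, or
#'   spec-ordered when `m` is `NULL`).
#' @export
generate_random_outgroup <- function(spec, m = NULL, seed = 1L,
                                     override = FALSE) {
  if (!inherits(spec, "outgroup_spec")) {
    abort("`spec` must be built with random_outgroup_spec().")
  }
  if (!is.null(m)) {
    n_dna <- sum(m$datatype == "dna")
    n_other <- n_char(m) - n_dna
    if (!override &&
        (n_dna != spec$n_nucleotides ||
         n_other != spec$n_morphology + spec$n_indel)) {
      abort(paste0("spec counts (", spec$n_nucleotides, " nt + ",
                   spec$n_morphology + spec$n_indel, " binary) do not match ",
                   "matrix layout (", n_dna, " dna + ", n_other,
                   " other characters); use override = TRUE to accept the ",
                   "matrix layout."))
    }
  } else {
    n_dna <- spec$n_nucleotides
    n_other <- spec$n_morphology + spec$n_indel
  }
  withr::with_seed(seed, {
    nt <- sample(DNA_SYMBOLS, n_dna, replace = TRUE,
                 prob = spec$base_frequencies)
    bin <- sample(c("0", "1"), n_other, replace = TRUE,
                  prob = c(1 - spec$binary_p, spec$binary_p))
  })
  if (is.null(m)) return(c(nt, bin))
  out <- character(n_char(m))
  out[m$datatype == "dna"] <- nt
  out[m$datatype != "dna"] <- bin
  out
}

#' Random-outgroup rooting survey
#'
#' The long-branch-attraction diagnostic: artificial outgroup taxa of random
#' composition are attached one at a time to the ingroup matrix, a heuristic
#' MP search is run for each, every optimal tree is rooted at the artificial
#' taxon, and the ingroup branch it attaches to is recorded. If the optimal
#' trees disagree on the attachment branch, the branch chosen by a majority
#' (>50%) of them is used; failing that the replicate counts as unresolved.
#' Random outgroups are expected to accumulate on the longest branches.
#'
#' @param m ingroup [char_matrix()] (at least 4 taxa).
#' @param spec an [random_outgroup_spec()]; its counts must match `m` (or set
#'   `override = TRUE`).
#' @param n_outgroups number of artificial taxa (replicates).
#' @param n_replicates random-addition replicates per search (the conventional
#'   setting is 25).
#' @param seed master seed; replicate `i` uses `seed + i`, so individual
#'   replicates can be reproduced in isolation.
#' @param max_trees equally-best tree buffer cap per search.
#' @param override passed to [generate_random_outgroup()].
#' @return an object of class `root_survey`: `counts` (tibble: `branch` — the
#'   canonical taxon-set key of the attachment bipartition — and `count`),
#'   `unresolved_count`, `n_total`, and `replicates` (per-replicate records:
#'   seed, best length, attachment branch, how it was resolved).
#' @export
survey_root <- function(m, spec = random_outgroup_spec(), n_outgroups = 100,
                        n_replicates = 25, seed = 1L, max_trees = 500,
                        override = FALSE) {
  if (n_taxa(m) < 4L) abort("ingroup matrix needs at least 4 taxa.")
  og_label <- "random_outgroup"
  while (og_label %in% m$taxa) og_label <- paste0(og_label, "_")
  ingroup <- sort(m$taxa)

  reps <- purrr::map_dfr(seq_len(n_outgroups), function(i) {
    rs <- seed + i
    row <- generate_random_outgroup(spec, m, seed = rs, override = override)
    mi <- add_taxon(m, og_label, row)
    sr <- heuristic_search(mi, n_replicates = n_replicates, seed = rs,
                           max_trees = max_trees)
    keys <- vapply(sr$binary_trees, attachment_branch, character(1),
                   outgroup = og_label, ingroup = ingroup)
    tab <- sort(table(keys), decreasing = TRUE)
    if (tab[1] == length(keys)) {
      resolved_by <- "strict"
      branch <- names(tab)[1]
    } else if (tab[1] > length(keys) / 2) {
      resolved_by <- "majority"
      branch <- names(tab)[1]
    } else {
      resolved_by <- "unresolved"
      branch <- NA_character_
    }
    tibble(replicate = i, seed = rs, best_length = sr$best_length,
           n_optimal = length(sr$binary_trees), branch = branch,
           resolved_by = resolved_by)
  })

  counts <- dplyr::count(dplyr::filter(reps, !is.na(.data$branch)),
                         .data$branch, name = "count")
  counts <- dplyr::arrange(counts, dplyr::desc(.data$count))
  structure(
    list(counts = counts,
         unresolved_count = sum(is.na(reps$branch)),
         n_total = n_outgroups,
         replicates = reps,
         ingroup = ingroup),
    class = "root_survey"
  )
}

#' @export
print.root_survey <- function(x, ...) {
  cat("<root_survey> ", x$n_total, " random outgroups; ",
      x$unresolved_count, " unresolved\n", sep = "")
  print(utils::head(x$counts, 5))
  invisible(x)
}

# Canonical key of the ingroup branch an outgroup tip attaches to: the
# bipartition of the ingroup induced by the outgroup's pendant edge, labeled
# by the side not containing the alphabetically first ingroup taxon.
attachment_branch <- function(tree, outgroup, ingroup) {
  og <- match(outgroup, tree$tip.label)
  n <- length(tree$tip.label)
  edge <- tree$edge
  adj <- vector("list", max(edge))
  for (e in seq_len(nrow(edge))) {
    adj[[edge[e, 1]]] <- c(adj[[edge[e, 1]]], edge[e, 2])
    adj[[edge[e, 2]]] <- c(adj[[edge[e, 2]]], edge[e, 1])
  }
  v <- adj[[og]][1] # the attachment node subdividing an ingroup branch
  kids <- setdiff(adj[[v]], og)
  # tips reachable from kids[1] without passing through v
  side <- character(0)
  stack <- kids[1]
  parent <- stats::setNames(v, kids[1])
  seen <- c(v, kids[1])
  while (length(stack)) {
    w <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (w <= n) side <- c(side, tree$tip.label[w])
    for (u in adj[[w]]) {
      if (!u %in% seen) {
        seen <- c(seen, u)
        stack <- c(stack, u)
      }
    }
  }
  other <- setdiff(ingroup, side)
  pick <- if (ingroup[1] %in% side) other else side
  paste(sort(pick), collapse = ";")
}

#' Classify a root-attachment branch against named clades
#'
#' Labels an attachment bipartition relative to reference clades: `"at X"`
#' when one side of the split is exactly clade X, `"within X"` when one side
#' is a proper subset of X, otherwise the branch's own bipartition key.
#' Clades are tested in the order given, so list more specific clades first.
#'
#' @param branch attachment key as produced by [survey_root()] (taxon labels
#'   joined by `";"`), or a character vector of taxa.
#' @param named_clades named list of taxon-label vectors.
#' @param ingroup all ingroup taxon labels.
#' @return a label string.
#' @export
classify_attachment <- function(branch, named_clades, ingroup) {
  side <- if (length(branch) == 1L) {
    strsplit(branch, ";", fixed = TRUE)[[1]]
  } else {
    as.character(branch)
  }
  other <- setdiff(ingroup, side)
  for (lab in names(named_clades)) {
    cl <- named_clades[[lab]]
    if (setequal(side, cl) || setequal(other, cl)) return(paste("at", lab))
  }
  for (lab in names(named_clades)) {
    cl <- named_clades[[lab]]
    if ((all(side %in% cl) && length(side) < length(cl)) ||
        (all(other %in% cl) && length(other) < length(cl))) {
      return(paste("within", lab))
    }
  }
  paste(sort(side), collapse = ";")
}

#' Tally a root survey against named clades
#'
#' @param survey a [survey_root()] result.
#' @param named_clades named list of taxon vectors ("at or within" groups).
#' @return tibble with `label` and `count` (plus an `unresolved` row).
#' @export
summarize_survey <- function(survey, named_clades) {
  labs <- vapply(survey$counts$branch, classify_attachment, character(1),
                 named_clades = named_clades, ingroup = survey$ingroup)
  out <- tibble(label = labs, count = survey$counts$count)
  out <- dplyr::summarise(dplyr::group_by(out, .data$label),
                          count = sum(.data$count), .groups = "drop")
  dplyr::arrange(
    dplyr::bind_rows(out, tibble(label = "unresolved",
                                 count = survey$unresolved_count)),
    dplyr::desc(.data$count)
  )
}
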