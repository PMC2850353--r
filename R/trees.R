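#' Read and write trees in newick format
#'
#' Thin wrappers around ape's newick reader/writer that return `phylo` /
#' `multiPhylo` objects. `write_newick()` can serialize a per-branch integer
#' annotation (e.g. ACCTRAN step counts) either as branch lengths
#' (`":<steps>"`) or as newick comments.
#'
#' @param file path to a newick file (one or more trees).
#' @param text newick text (alternative to `file`).
#' @param tree a `phylo` object.
#' @param trees a `phylo` or `multiPhylo` object.
#' @param annotations optional numeric vector of per-branch values, one per row
#'   of `tree$edge` (names, if present, must be edge indices).
#' @param annotation_style `"lengths"` writes annotations as branch lengths,
#'   `"comments"` as `[&steps=..]` comments after each branch.
#' @return `read_newick()`: a `phylo` (single tree) or `multiPhylo`;
#'   `write_newick()`: the newick text, invisibly when written to a file.
#' @export
read_newick <- function(file = NULL, text = NULL) {
  tr <- ape::read.tree(file = file, text = text)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(trees, file = NULL, annotations = NULL,
                         annotation_style = c("lengths", "comments")) {
  annotation_style <- match.arg(annotation_style)
  if (!is.null(annotations)) {
    if (inherits(trees, "multiPhylo")) {
      abort("annotations can only be written for a single tree.")
    }
    tree <- trees
    idx <- if (!is.null(names(annotations))) {
      as.integer(names(annotations))
    } else {
      seq_along(annotations)
    }
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(tree$edge))) {
      abort("annotation refers to a non-existent branch.")
    }
    if (annotation_style == "lengths") {
      tree$edge.length <- rep(0, nrow(tree$edge))
      tree$edge.length[idx] <- annotations
      text <- ape::write.tree(tree)
    } else {
      tree$edge.length <- NULL
      text <- ape::write.tree(tree)
      # inject comments tipward: simplest robust path is lengths-style; emit
      # comment form by rewriting ":x" tokens
      tree$edge.length <- rep(0, nrow(tree$edge))
      tree$edge.length[idx] <- annotations
      text <- ape::write.tree(tree)
      text <- gsub(":([0-9.eE+-]+)", "[&steps=\\1]", text)
    }
  } else {
    text <- ape::write.tree(trees)
  }
  if (is.null(file)) return(text)
  writeLines(text, file)
  invisible(text)
}

# ---- internal tree helpers -------------------------------------------------

# Coerce to an unrooted tree whose tips match the matrix taxa; returns list
# with the edge matrix and the permutation mapping matrix rows -> tree tips.
prepare_tree <- function(tree, m) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object.")
  missing <- setdiff(tree$tip.label, m$taxa)
  if (length(missing)) {
    abort(paste0("tree leaves absent from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  tree <- ape::unroot(tree)
  tree
}

is_binary_unrooted <- function(tree) {
  n <- length(tree$tip.label)
  tree$Nnode == n - 2L
}

# phylo from a C++ edge matrix whose tip ids index `labels`
phylo_from_edge <- function(edge, labels) {
  n <- length(labels)
  tr <- structure(
    list(edge = edge, tip.label = labels, Nnode = max(edge) - n),
    class = "phylo", order = "cladewise"
  )
  tr <- stats::reorder(tr)
  tr
}

# Canonical topology key (split-set hash) for deduplication; works for
# multifurcating unrooted trees. Taxon label order is normalized first.
topology_key <- function(tree, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(tree$tip.label)
  keys <- tree_split_keys(tree, taxa)
  paste(sort(keys), collapse = "&")
}

# Nontrivial splits of a tree as canonical string keys: each split is
# represented by the sorted labels of the side NOT containing taxa[1].
tree_split_keys <- function(tree, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    split_key(side, taxa)
  }, character(1))
  keys <- keys[!is.na(keys)]
  unique(keys)
}

# Canonical key of one bipartition side; NA for trivial splits.
split_key <- function(side, taxa) {
  n <- length(taxa)
  if (taxa[1] %in% side) side <- setdiff(taxa, side)
  k <- length(side)
  if (k < 2L || k > n - 2L) return(NA_character_)
  paste(sort(side), collapse = ";")
}

#' Does a tree display a clade?
#'
#' A clade (taxon subset) is displayed when some branch of the unrooted tree
#' bipartitions the leaf set into the clade versus the rest.
#'
#' @param tree a `phylo`.
#' @param clade character vector of taxon labels (a proper subset of the
#'   tree's tips, of size 2 to n-2).
#' @return logical.
#' @export
has_clade <- function(tree, clade) {
  taxa <- sort(tree$tip.label)
  key <- split_key(clade, taxa)
  if (is.na(key)) abort("clade must contain 2 to n-2 of the tree's tips.")
  key %in% tree_split_keys(tree, taxa)
}

#' Collapse branches without unambiguous support (MINBRLEN rule)
#'
#' Deletes every internal branch whose minimum possible length over all
#' most-parsimonious reconstructions of `m` on the tree is zero — branches
#' that lack even one unambiguous character-state change. This reproduces
#' PAUP*'s `COLLAPSE=MINBRLEN` behaviour.
#'
#' @param tree an unrooted binary `phylo`.
#' @param m the [char_matrix()] used for scoring.
#' @return a `phylo`, possibly multifurcating.
#' @export
collapse_minbrlen <- function(tree, m) {
  tree <- prepare_tree(tree, m)
  if (!is_binary_unrooted(tree)) {
    abort("collapse_minbrlen() expects a fully resolved (binary) unrooted tree.")
  }
  masks <- fitch_masks(m)[match(tree$tip.label, m$taxa), , drop = FALSE]
  mins <- branch_min_cpp(tree$edge, length(tree$tip.label),
                         masks, m$weights)
  n <- length(tree$tip.label)
  internal <- tree$edge[, 2] > n
  drop <- internal & mins == 0L
  if (!any(drop)) return(tree)
  tree$edge.length <- ifelse(drop, 0, 1)
  out <- ape::di2multi(tree, tol = 0.5)
  out$edge.length <- NULL
  out
}
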