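#' @useDynLib parsmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom ape read.tree write.tree unroot di2multi prop.part rtopology
NULL

DNA_SYMBOLS <- c("A", "C", "G", "T")

# IUPAC ambiguity codes expand to state sets; gap and '?' are missing.
DNA_AMBIGUITY <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), X = c("A", "C", "G", "T")
)

#' Mixed-datatype character matrix
#'
#' Builds the central container for parsimony analysis: a taxa-by-characters
#' matrix in which each cell holds a *state set* — a singleton for an observed
#' state, several states for a polymorphic or ambiguous observation, or the
#' empty set for missing data. Characters carry a datatype (`"dna"`,
#' `"standard"` or `"binary"`), a non-negative integer weight, and belong to
#' exactly one named partition.
#'
#' Cells are written as strings: `"A"`, `"0"` (singleton), `"AG"`, `"01"`
#' (polymorphic/ambiguous set), `"?"` or `"-"` (missing; the gap symbol in DNA
#' is treated as missing data). IUPAC ambiguity codes in DNA cells are expanded
#' to their state sets (`R` to `{A,G}` and so on).
#'
#' @param cells character matrix (taxa in rows, characters in columns) of cell
#'   strings as described above; row names are taxon labels.
#' @param datatype character vector, one of `"dna"`, `"standard"`, `"binary"`,
#'   recycled along characters.
#' @param weights non-negative integer weights, recycled; default 1.
#' @param partitions named list of 1-based character index vectors; must be
#'   disjoint and cover all characters. Default: a single partition `"all"`.
#' @param taxa taxon labels; defaults to `rownames(cells)`.
#' @return an object of class `char_matrix`.
#' @examples
#' m <- char_matrix(
#'   rbind(t1 = c("A", "0"), t2 = c("G", "1"), t3 = c("-", "01"), t4 = c("A", "?")),
#'   datatype = c("dna", "standard")
#' )
#' m
#' @export
char_matrix <- function(cells, datatype = "standard", weights = 1L,
                        partitions = NULL, taxa = rownames(cells)) {
  if (!is.matrix(cells) || !is.character(cells)) {
    abort("`cells` must be a character matrix of cell strings.")
  }
  nch <- ncol(cells)
  nt <- nrow(cells)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nt))
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon label: ", taxa[duplicated(taxa)][1]))
  }
  datatype <- rep_len(match.arg(datatype, c("dna", "standard", "binary"),
                                several.ok = TRUE), nch)
  weights <- rep_len(as.integer(weights), nch)
  if (any(weights < 0L)) abort("character weights must be non-negative.")
  if (is.null(partitions)) partitions <- list(all = seq_len(nch))
  check_partitions(partitions, nch)

  parsed <- lapply(seq_len(nch), function(j) {
    parse_cell_column(cells[, j], datatype[j], j, taxa)
  })
  masks <- vapply(parsed, `[[`, integer(nt), "masks")
  if (nt == 1L) masks <- matrix(masks, nrow = 1L)
  symbols <- lapply(parsed, `[[`, "symbols")

  new_char_matrix(taxa, masks, symbols, datatype, weights, partitions)
}

new_char_matrix <- function(taxa, masks, symbols, datatype, weights, partitions) {
  structure(
    list(
      taxa = as.character(taxa),
      masks = masks,
      symbols = symbols,
      datatype = datatype,
      weights = weights,
      partitions = lapply(partitions, as.integer)
    ),
    class = "char_matrix"
  )
}

check_partitions <- function(partitions, nch) {
  if (is.null(names(partitions)) || any(!nzchar(names(partitions)))) {
    abort("partitions must be a *named* list of character indices.")
  }
  idx <- sort(unlist(partitions, use.names = FALSE))
  if (length(idx) != nch || any(idx != seq_len(nch))) {
    abort("partition index sets must be disjoint and together cover all characters.")
  }
  invisible(TRUE)
}

# Parse one character's column of cell strings into bitmasks plus the
# character's state universe (bit order = order of `symbols`).
parse_cell_column <- function(col, datatype, j, taxa) {
  sets <- lapply(seq_along(col), function(i) {
    expand_cell(col[i], datatype, j, taxa[i])
  })
  if (datatype == "dna") {
    symbols <- DNA_SYMBOLS
  } else {
    symbols <- sort(unique(unlist(sets)))
    if (length(symbols) == 0L) symbols <- "0" # all-missing character
    if (length(symbols) > 30L) {
      abort(paste0("character ", j, " has more than 30 states."))
    }
  }
  masks <- vapply(sets, function(s) {
    if (length(s) == 0L) return(0L) # missing
    sum(bitwShiftL(1L, match(s, symbols) - 1L))
  }, integer(1))
  list(masks = masks, symbols = symbols)
}

# One cell string -> character vector of states ("" / "?" / "-" -> missing).
expand_cell <- function(cell, datatype, j, taxon) {
  cell <- gsub("[(){} ]", "", cell)
  if (cell %in% c("?", "", "-") && datatype != "dna") {
    return(character(0))
  }
  states <- strsplit(toupper(cell), "")[[1]]
  if (datatype == "dna") {
    out <- character(0)
    for (s in states) {
      if (s %in% c("-", "?", ".")) next # gap treated as missing
      exp <- DNA_AMBIGUITY[[s]]
      if (is.null(exp)) {
        abort(paste0("unknown state symbol '", s, "' in character ", j,
                     " (taxon ", taxon, ")."))
      }
      out <- c(out, exp)
    }
    return(unique(out))
  }
  if (any(states == "?") || any(states == "-")) {
    states <- states[!states %in% c("?", "-")]
    if (length(states) == 0L) return(character(0))
  }
  bad <- !grepl("^[A-Z0-9]$", states)
  if (any(bad)) {
    abort(paste0("unknown state symbol '", states[bad][1], "' in character ", j,
                 " (taxon ", taxon, ")."))
  }
  unique(states)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", length(x$taxa), " taxa x ", n_char(x), " characters\n",
      sep = "")
  tab <- table(x$datatype)
  cat("  datatypes: ", paste0(names(tab), "=", tab, collapse = ", "), "\n", sep = "")
  cat("  partitions: ",
      paste0(names(x$partitions), " (", lengths(x$partitions), ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of taxa / characters
#' @param m a `char_matrix`.
#' @return integer count.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_char <- function(m) ncol(m$masks)

#' Recover cell strings from a character matrix
#'
#' Inverse of the cell encoding used by [char_matrix()]: singleton sets print
#' as their symbol, multi-state sets as the concatenated symbols, missing cells
#' as `"?"`.
#'
#' @param m a `char_matrix`.
#' @return character matrix with taxa as row names.
#' @export
cell_strings <- function(m) {
  out <- matrix("", n_taxa(m), n_char(m), dimnames = list(m$taxa, NULL))
  for (j in seq_len(n_char(m))) {
    syms <- m$symbols[[j]]
    out[, j] <- vapply(m$masks[, j], function(mask) {
      if (mask == 0L) return("?")
      paste0(syms[bitwAnd(bitwShiftL(1L, seq_along(syms) - 1L), mask) != 0L],
             collapse = "")
    }, character(1))
  }
  out
}

#' Extract a sub-matrix restricted to a partition or taxon set
#'
#' @param m a `char_matrix`.
#' @param partition partition name, or `NULL` to keep all characters.
#' @param taxa taxon labels to keep, or `NULL` to keep all.
#' @return a `char_matrix`. When restricted to one partition the result has a
#'   single partition of that name; taxon restriction preserves all partitions.
#' @export
restrict_matrix <- function(m, partition = NULL, taxa = NULL) {
  keep_t <- seq_len(n_taxa(m))
  if (!is.null(taxa)) {
    keep_t <- match(taxa, m$taxa)
    if (anyNA(keep_t)) {
      abort(paste0("taxa not in matrix: ",
                   paste(taxa[is.na(keep_t)], collapse = ", ")))
    }
  }
  keep_c <- seq_len(n_char(m))
  parts <- m$partitions
  if (!is.null(partition)) {
    keep_c <- partition_indices(m, partition)
    parts <- stats::setNames(list(seq_along(keep_c)),
                             paste(partition, collapse = "+"))
  } else if (!is.null(taxa)) {
    parts <- m$partitions
  }
  new_char_matrix(
    m$taxa[keep_t],
    m$masks[keep_t, keep_c, drop = FALSE],
    m$symbols[keep_c],
    m$datatype[keep_c],
    m$weights[keep_c],
    parts
  )
}

partition_indices <- function(m, partition) {
  bad <- setdiff(partition, names(m$partitions))
  if (length(bad)) {
    abort(paste0("unknown partition: ", paste(bad, collapse = ", "),
                 " (have: ", paste(names(m$partitions), collapse = ", "), ")"))
  }
  sort(unlist(m$partitions[partition], use.names = FALSE))
}

#' Append a taxon row to a character matrix
#'
#' @param m a `char_matrix`.
#' @param label new taxon label.
#' @param cells character vector of cell strings, one per character, in the
#'   same cell syntax as [char_matrix()].
#' @return a `char_matrix` with one more taxon.
#' @export
add_taxon <- function(m, label, cells) {
  if (label %in% m$taxa) abort(paste0("duplicate taxon label: ", label))
  if (length(cells) != n_char(m)) {
    abort("`cells` must have one entry per character.")
  }
  masks <- integer(n_char(m))
  symbols <- m$symbols
  for (j in seq_len(n_char(m))) {
    states <- expand_cell(cells[j], m$datatype[j], j, label)
    if (length(states) == 0L) {
      masks[j] <- 0L
      next
    }
    extra <- setdiff(states, symbols[[j]])
    if (length(extra)) symbols[[j]] <- c(symbols[[j]], extra)
    masks[j] <- sum(bitwShiftL(1L, match(states, symbols[[j]]) - 1L))
  }
  new_char_matrix(c(m$taxa, label), rbind(m$masks, masks), symbols,
                  m$datatype, m$weights, m$partitions)
}

# Leaf masks with missing recoded as the full state set (Fitch convention).
fitch_masks <- function(m, chars = seq_len(n_char(m))) {
  masks <- m$masks[, chars, drop = FALSE]
  full <- vapply(m$symbols[chars], function(s) {
    bitwShiftL(1L, length(s)) - 1L
  }, integer(1))
  for (j in seq_along(chars)) {
    mj <- masks[, j]
    mj[mj == 0L] <- full[j]
    masks[, j] <- mj
  }
  masks
}
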