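#' Parse a NEXUS document into a character matrix
#'
#' Reads DATA/CHARACTERS blocks (sequential or interleaved) with DNA, STANDARD
#' or RESTRICTION/binary datatypes, including MrBayes-style
#' `DATATYPE=MIXED(DNA:1-913,STANDARD:914-1058,...)` declarations. `CHARSET`
#' statements (in SETS, ASSUMPTIONS or program blocks) become named partitions;
#' `WTSET` statements set integer character weights. Parenthesised or braced
#' cells become polymorphic state sets, `?` becomes missing, and the gap symbol
#' `-` in DNA is treated as missing data. All other command blocks (PAUP,
#' MrBayes, TREES, ...) are ignored.
#'
#' @param text a single string, or character vector of lines, containing the
#'   NEXUS document.
#' @return a [char_matrix()].
#' @seealso [read_nexus_matrix()] to read from a file, [write_nexus_matrix()]
#'   for the inverse.
#' @export
parse_nexus <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  text <- strip_nexus_comments(text)
  if (!grepl("#NEXUS", text, ignore.case = TRUE)) {
    abort("not a NEXUS document (missing #NEXUS header).")
  }

  blocks <- extract_blocks(text)
  data_blocks <- blocks[toupper(names(blocks)) %in% c("DATA", "CHARACTERS")]
  if (length(data_blocks) == 0L) {
    abort("NEXUS document contains no DATA or CHARACTERS block.")
  }

  pieces <- lapply(data_blocks, parse_characters_block)
  taxa <- pieces[[1]]$taxa
  for (p in pieces[-1]) {
    if (!setequal(p$taxa, taxa)) {
      abort("CHARACTERS blocks list different taxon sets.")
    }
  }
  cells <- do.call(cbind, lapply(pieces, function(p) p$cells[taxa, , drop = FALSE]))
  datatype <- unlist(lapply(pieces, `[[`, "datatype"), use.names = FALSE)
  nch <- ncol(cells)

  charsets <- list()
  weights <- rep(1L, nch)
  for (i in seq_along(blocks)) {
    cmds <- blocks[[i]]
    charsets <- c(charsets, parse_charsets(cmds, nch))
    weights <- apply_wtsets(cmds, weights)
  }
  partitions <- charsets_to_partitions(charsets, nch)

  char_matrix(cells, datatype = datatype, weights = weights,
              partitions = partitions, taxa = taxa)
}

#' Read / write a character matrix in NEXUS format
#'
#' `write_nexus_matrix()` emits a single CHARACTERS block with a
#' `DATATYPE=MIXED(...)` declaration, one `CHARSET` per partition and a
#' `WTSET` when any weight differs from 1; `read_nexus_matrix()` (and
#' [parse_nexus()]) read that form back so that cells, datatypes, weights and
#' partitions round-trip exactly. Multi-state DNA cells are written as IUPAC
#' ambiguity codes; multi-state standard cells as `(01)`.
#'
#' @param file path to a NEXUS file.
#' @param m a [char_matrix()].
#' @return `read_nexus_matrix()`: a `char_matrix`. `write_nexus_matrix()`: the
#'   NEXUS text, invisibly when written to a file.
#' @export
read_nexus_matrix <- function(file) {
  parse_nexus(readLines(file, warn = FALSE))
}

#' @rdname read_nexus_matrix
#' @export
write_nexus_matrix <- function(m, file = NULL) {
  cells <- cell_strings(m)
  nch <- n_char(m)
  # serialize each cell; DNA sets -> IUPAC, standard sets -> (..)
  iupac_rev <- stats::setNames(
    names(DNA_AMBIGUITY),
    vapply(DNA_AMBIGUITY, function(s) paste(sort(s), collapse = ""), character(1))
  )
  iupac_rev[["T"]] <- "T" # prefer T over U
  out <- cells
  for (j in seq_len(nch)) {
    multi <- nchar(cells[, j]) > 1L
    if (any(multi)) {
      if (m$datatype[j] == "dna") {
        key <- vapply(strsplit(cells[multi, j], ""), function(s) {
          paste(sort(s), collapse = "")
        }, character(1))
        out[multi, j] <- unname(iupac_rev[key])
      } else {
        out[multi, j] <- paste0("(", cells[multi, j], ")")
      }
    }
  }
  rows <- apply(out, 1L, paste0, collapse = "")

  dt_runs <- rle(m$datatype)
  ends <- cumsum(dt_runs$lengths)
  starts <- ends - dt_runs$lengths + 1L
  dt_names <- c(dna = "DNA", standard = "STANDARD", binary = "RESTRICTION")
  mixed <- paste0(dt_names[dt_runs$values], ":", starts,
                  ifelse(dt_runs$lengths > 1L, paste0("-", ends), ""),
                  collapse = ",")

  std <- unique(unlist(m$symbols[m$datatype != "dna"]))
  sym_decl <- if (length(std)) {
    paste0(" SYMBOLS=\"", paste(sort(std), collapse = ""), "\"")
  } else ""

  pad <- max(nchar(m$taxa)) + 2L
  lines <- c(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    paste0("  DIMENSIONS NTAX=", n_taxa(m), " NCHAR=", nch, ";"),
    paste0("  FORMAT DATATYPE=MIXED(", mixed, ") MISSING=? GAP=-", sym_decl, ";"),
    "  MATRIX",
    paste0("    ", formatC(m$taxa, width = -pad), rows),
    "  ;",
    "END;",
    "BEGIN SETS;",
    vapply(names(m$partitions), function(p) {
      paste0("  CHARSET ", p, " = ", compress_ranges(m$partitions[[p]]), ";")
    }, character(1))
  )
  if (any(m$weights != 1L)) {
    wl <- vapply(sort(unique(m$weights)), function(w) {
      paste0(w, ": ", compress_ranges(which(m$weights == w)))
    }, character(1))
    lines <- c(lines, paste0("  WTSET * parsmix_weights = ",
                             paste(wl, collapse = ", "), ";"))
  }
  lines <- c(lines, "END;")
  text <- paste(lines, collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(text, file)
  invisible(text)
}

# ---- internals ---------------------------------------------------------------

strip_nexus_comments <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  keep <- logical(length(chars))
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1L
    keep[i] <- depth == 0L
    if (chars[i] == "]" && depth > 0L) depth <- depth - 1L
  }
  paste(chars[keep], collapse = "")
}

# Returns a named list of block bodies (names = block names, upper-cased kept
# as written); each body is the text between BEGIN <name>; and END;.
extract_blocks <- function(text) {
  m <- gregexpr("(?is)\\bBEGIN\\s+(\\w+)\\s*;(.*?)\\bEND(?:BLOCK)?\\s*;",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list())
  starts <- attr(m, "capture.start")
  lens <- attr(m, "capture.length")
  out <- list()
  for (k in seq_along(m)) {
    nm <- substr(text, starts[k, 1], starts[k, 1] + lens[k, 1] - 1L)
    body <- substr(text, starts[k, 2], starts[k, 2] + lens[k, 2] - 1L)
    out[[length(out) + 1L]] <- body
    names(out)[length(out)] <- nm
  }
  out
}

split_commands <- function(body) {
  cmds <- strsplit(body, ";", fixed = TRUE)[[1]]
  cmds <- trimws(cmds)
  cmds[nzchar(cmds)]
}

parse_characters_block <- function(body) {
  cmds <- split_commands(body)
  up <- toupper(cmds)

  nchar_decl <- NA_integer_
  ntax_decl <- NA_integer_
  dim_cmd <- cmds[grepl("^DIMENSIONS", up)]
  if (length(dim_cmd)) {
    if (grepl("NCHAR", toupper(dim_cmd[1]))) {
      nchar_decl <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1",
                                   toupper(dim_cmd[1])))
    }
    if (grepl("NTAX", toupper(dim_cmd[1]))) {
      ntax_decl <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1",
                                  toupper(dim_cmd[1])))
    }
  }

  datatype_spec <- "standard"
  mixed_spec <- NULL
  interleave <- FALSE
  fmt_cmd <- cmds[grepl("^FORMAT", up)]
  if (length(fmt_cmd)) {
    fmt <- fmt_cmd[1]
    interleave <- grepl("(?i)INTERLEAVE", fmt, perl = TRUE) &&
      !grepl("(?i)INTERLEAVE\\s*=\\s*NO", fmt, perl = TRUE)
    mm <- regmatches(fmt, regexpr("(?i)DATATYPE\\s*=\\s*MIXED\\s*\\(([^)]*)\\)",
                                  fmt, perl = TRUE))
    if (length(mm)) {
      inner <- sub("(?i).*\\(([^)]*)\\).*", "\\1", mm, perl = TRUE)
      mixed_spec <- parse_mixed_spec(inner)
    } else {
      dt <- regmatches(fmt, regexpr("(?i)DATATYPE\\s*=\\s*(\\w+)", fmt, perl = TRUE))
      if (length(dt)) {
        datatype_spec <- map_datatype(sub(".*=\\s*", "", toupper(dt)))
      }
    }
  }

  mat_i <- which(grepl("^MATRIX\\b", up))
  if (length(mat_i) == 0L) abort("CHARACTERS block has no MATRIX command.")
  mat_text <- sub("(?i)^MATRIX", "", cmds[mat_i[1]], perl = TRUE)
  rows <- parse_matrix_rows(mat_text, interleave = interleave)
  taxa <- names(rows)

  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1L) {
    off <- taxa[lens != stats::median(lens)]
    abort(paste0("ragged matrix: taxon ", off[1], " has ", lens[taxa == off[1]][1],
                 " characters where others have ", stats::median(lens), "."))
  }
  nch <- unname(lens[1])
  if (!is.na(nchar_decl) && nch != nchar_decl) {
    abort(paste0("matrix rows have ", nch, " characters but NCHAR=", nchar_decl, "."))
  }
  if (!is.na(ntax_decl) && length(taxa) != ntax_decl) {
    warn(paste0("matrix has ", length(taxa), " taxa but NTAX=", ntax_decl,
                "; trusting the matrix."))
  }

  datatype <- rep(datatype_spec, nch)
  if (!is.null(mixed_spec)) {
    datatype <- rep(NA_character_, nch)
    for (k in seq_len(nrow(mixed_spec))) {
      datatype[mixed_spec$from[k]:mixed_spec$to[k]] <- mixed_spec$datatype[k]
    }
    if (anyNA(datatype)) {
      abort("DATATYPE=MIXED(...) ranges do not cover all characters.")
    }
  }

  cells <- do.call(rbind, rows)
  rownames(cells) <- taxa
  list(taxa = taxa, cells = cells, datatype = datatype)
}

map_datatype <- function(x) {
  switch(x,
    DNA = "dna", NUCLEOTIDE = "dna", RNA = "dna",
    STANDARD = "standard",
    RESTRICTION = "binary", BINARY = "binary",
    abort(paste0("unsupported DATATYPE: ", x))
  )
}

parse_mixed_spec <- function(inner) {
  parts <- strsplit(inner, ",")[[1]]
  out <- lapply(parts, function(p) {
    p <- trimws(p)
    nm <- map_datatype(toupper(sub("\\s*:.*", "", p)))
    rng <- sub(".*:\\s*", "", p)
    if (grepl("-", rng)) {
      ab <- as.integer(strsplit(rng, "-")[[1]])
    } else {
      ab <- rep(as.integer(rng), 2L)
    }
    data.frame(datatype = nm, from = ab[1], to = ab[2])
  })
  do.call(rbind, out)
}

# Tokenize a MATRIX body into per-taxon cell vectors. With `interleave`,
# repeated taxon labels append; otherwise a repeat is a duplicate-label error.
parse_matrix_rows <- function(mat_text, interleave = FALSE) {
  lines <- strsplit(mat_text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- list()
  order_seen <- character(0)
  for (ln in lines) {
    if (grepl("^'", ln)) {
      label <- sub("^'([^']*)'.*", "\\1", ln)
      rest <- sub("^'[^']*'", "", ln)
    } else {
      label <- sub("^(\\S+).*", "\\1", ln)
      rest <- sub("^\\S+", "", ln)
    }
    cells <- tokenize_cells(gsub("\\s", "", rest))
    if (!label %in% order_seen) {
      order_seen <- c(order_seen, label)
      rows[[label]] <- cells
    } else if (interleave) {
      rows[[label]] <- c(rows[[label]], cells)
    } else {
      abort(paste0("duplicate taxon label: ", label))
    }
  }
  rows[order_seen]
}

tokenize_cells <- function(s) {
  if (!nzchar(s)) return(character(0))
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      j <- i + 1L
      while (j <= n && chars[j] != close) j <- j + 1L
      if (j > n) abort("unbalanced parenthesis in matrix cell.")
      out <- c(out, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

parse_charsets <- function(cmds_body, nch) {
  cmds <- split_commands(cmds_body)
  cs <- cmds[grepl("^CHARSET\\b", toupper(cmds))]
  out <- list()
  for (cmd in cs) {
    nm <- sub("(?i)^CHARSET\\s+(\\S+)\\s*=.*", "\\1", cmd, perl = TRUE)
    rng <- sub(".*=\\s*", "", cmd)
    out[[nm]] <- parse_index_list(rng, nch)
  }
  out
}

apply_wtsets <- function(cmds_body, weights) {
  cmds <- split_commands(cmds_body)
  ws <- cmds[grepl("^WTSET\\b", toupper(cmds))]
  for (cmd in ws) {
    spec <- sub(".*=\\s*", "", cmd)
    for (piece in strsplit(spec, ",")[[1]]) {
      bits <- strsplit(piece, ":", fixed = TRUE)[[1]]
      if (length(bits) != 2L) next
      w <- as.integer(trimws(bits[1]))
      idx <- parse_index_list(bits[2], length(weights))
      weights[idx] <- w
    }
  }
  weights
}

# "1-3 7 10-12" (with optional ".") -> integer indices
parse_index_list <- function(s, nch) {
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  idx <- integer(0)
  for (t in toks) {
    if (t == ".") {
      idx <- c(idx, nch)
    } else if (grepl("-", t)) {
      ab <- strsplit(t, "-")[[1]]
      to <- if (ab[2] == ".") nch else as.integer(ab[2])
      idx <- c(idx, as.integer(ab[1]):to)
    } else {
      idx <- c(idx, as.integer(t))
    }
  }
  if (any(idx < 1L | idx > nch)) {
    abort("charset index out of range.")
  }
  idx
}

charsets_to_partitions <- function(charsets, nch) {
  if (length(charsets) == 0L) return(list(all = seq_len(nch)))
  idx <- unlist(charsets, use.names = FALSE)
  if (anyDuplicated(idx)) {
    warn("overlapping charsets; ignoring charsets and using a single partition.")
    return(list(all = seq_len(nch)))
  }
  rest <- setdiff(seq_len(nch), idx)
  if (length(rest)) charsets$unassigned <- rest
  charsets
}

compress_ranges <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, character(1)), collapse = " ")
}
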