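#' Simulation configuration for mixed matrices
#'
#' Describes a mixed DNA + morphology + indel matrix evolved on a known tree:
#' DNA under an HKY-like process (fixed base frequencies, a
#' transition/transversion rate ratio, optionally discretized-gamma rate
#' heterogeneity with 4 categories), morphology under an Mk-type process with
#' 2-4 states per character, and indels as binary Mk characters. Missing and
#' polymorphic cells are injected afterwards at stated fractions. The default
#' configuration mirrors a realistic single-nuclear-locus study: 913 sites
#' with base frequencies A 0.2805, C 0.265, G 0.2218, T 0.2327 and gamma
#' shape 0.8383, 144 morphological and 8 indel characters.
#'
#' @param n_taxa number of taxa (ignored when `tree` is supplied).
#' @param tree optional `phylo` with branch lengths in expected
#'   substitutions per character; default: a random topology with all branch
#'   lengths equal to `branch_length`.
#' @param branch_length expected substitutions per character per branch for
#'   the default tree.
#' @param n_sites number of DNA sites.
#' @param base_frequencies numeric simplex over A, C, G, T.
#' @param kappa transition/transversion rate ratio of the HKY process.
#' @param gamma_shape shape of the discretized gamma across sites
#'   (`NULL` = rate homogeneity).
#' @param n_morph number of morphological characters.
#' @param morph_states possible state counts per morphological character.
#' @param morph_state_probs sampling weights for `morph_states`.
#' @param morph_rate,indel_rate rate multipliers relative to the DNA process.
#' @param n_indel number of binary indel characters.
#' @param missing_fraction fraction of cells recoded as missing.
#' @param polymorphic_fraction fraction of cells replaced by a two-state set
#'   containing the true state (a testing device, not a biological model).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 30, tree = NULL, branch_length = 0.05,
                       n_sites = 913,
                       base_frequencies = c(A = 0.2805, C = 0.265,
                                            G = 0.2218, T = 0.2327),
                       kappa = 4.6, gamma_shape = 0.8383,
                       n_morph = 144, morph_states = c(2, 3, 4),
                       morph_state_probs = c(0.7, 0.25, 0.05),
                       morph_rate = 1, indel_rate = 0.5, n_indel = 8,
                       missing_fraction = 0.1, polymorphic_fraction = 0.01) {
  if (abs(sum(base_frequencies) - 1) > 1e-6) {
    abort("base frequencies must sum to 1.")
  }
  if (kappa <= 0 || (!is.null(gamma_shape) && gamma_shape <= 0) ||
      morph_rate <= 0 || indel_rate <= 0) {
    abort("rates must be positive.")
  }
  if (missing_fraction < 0 || missing_fraction > 1 ||
      polymorphic_fraction < 0 || polymorphic_fraction > 1) {
    abort("cell fractions must lie in [0, 1].")
  }
  if (is.null(tree) && n_taxa < 4) abort("need at least 4 taxa.")
  structure(
    list(n_taxa = if (is.null(tree)) as.integer(n_taxa) else length(tree$tip.label),
         tree = tree, branch_length = branch_length, n_sites = as.integer(n_sites),
         base_frequencies = base_frequencies[DNA_SYMBOLS], kappa = kappa,
         gamma_shape = gamma_shape, n_morph = as.integer(n_morph),
         morph_states = as.integer(morph_states),
         morph_state_probs = morph_state_probs, morph_rate = morph_rate,
         indel_rate = indel_rate, n_indel = as.integer(n_indel),
         missing_fraction = missing_fraction,
         polymorphic_fraction = polymorphic_fraction),
    class = "sim_config"
  )
}

#' Simulate a mixed character matrix on a known tree
#'
#' Evolves DNA, morphological and indel partitions along the (given or
#' randomly generated) tree per a [sim_config()], then injects missing and
#' polymorphic cells, and returns both the matrix — with partitions named
#' `GHR`, `morphology` and `indels` — and the generating tree. Deterministic
#' under `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with elements `matrix` (a [char_matrix()]) and `tree` (the
#'   true `phylo`).
#' @export
simulate_matrix <- function(config, seed = 1L) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be built with sim_config().")
  }
  withr::with_seed(seed, {
    tree <- config$tree
    if (is.null(tree)) {
      tree <- ape::rtopology(config$n_taxa, rooted = FALSE,
                             tip.label = paste0("t", seq_len(config$n_taxa)))
      tree$edge.length <- rep(config$branch_length, nrow(tree$edge))
    }
    taxa <- tree$tip.label

    cells <- NULL
    datatype <- character(0)

    if (config$n_sites > 0L) {
      Q <- c(1, config$kappa, 1, 1, config$kappa, 1)
      if (is.null(config$gamma_shape)) {
        dna <- sim_phydat(tree, config$n_sites, type = "DNA", Q = Q,
                          bf = config$base_frequencies, rate = 1)
      } else {
        rates <- phangorn::discrete.gamma(config$gamma_shape, 4)
        cat_of <- sample.int(4, config$n_sites, replace = TRUE)
        dna <- matrix("", length(taxa), config$n_sites,
                      dimnames = list(taxa, NULL))
        for (g in seq_len(4)) {
          ns <- sum(cat_of == g)
          if (ns == 0L) next
          dna[, cat_of == g] <- sim_phydat(tree, ns, type = "DNA", Q = Q,
                                           bf = config$base_frequencies,
                                           rate = rates[g])
        }
      }
      cells <- cbind(cells, dna)
      datatype <- c(datatype, rep("dna", config$n_sites))
    }

    if (config$n_morph > 0L) {
      k_of <- sample(config$morph_states, config$n_morph, replace = TRUE,
                     prob = config$morph_state_probs)
      morph <- matrix("", length(taxa), config$n_morph,
                      dimnames = list(taxa, NULL))
      for (k in unique(k_of)) {
        nk <- sum(k_of == k)
        morph[, k_of == k] <- sim_phydat(tree, nk, type = "USER",
                                         levels = as.character(0:(k - 1)),
                                         rate = config$morph_rate)
      }
      cells <- cbind(cells, morph)
      datatype <- c(datatype, rep("standard", config$n_morph))
    }

    if (config$n_indel > 0L) {
      ind <- sim_phydat(tree, config$n_indel, type = "USER",
                        levels = c("0", "1"), rate = config$indel_rate)
      cells <- cbind(cells, ind)
      datatype <- c(datatype, rep("binary", config$n_indel))
    }

    # inject missing, then polymorphic cells
    nc <- length(cells)
    if (config$missing_fraction > 0) {
      hit <- which(stats::runif(nc) < config$missing_fraction)
      cells[hit] <- "?"
    }
    if (config$polymorphic_fraction > 0) {
      for (j in seq_len(ncol(cells))) {
        universe <- if (datatype[j] == "dna") DNA_SYMBOLS else {
          sort(unique(cells[, j][cells[, j] != "?"]))
        }
        if (length(universe) < 2L) next
        hit <- which(stats::runif(nrow(cells)) < config$polymorphic_fraction &
                       cells[, j] != "?")
        for (i in hit) {
          other <- sample(setdiff(universe, cells[i, j]), 1L)
          cells[i, j] <- paste0(sort(c(cells[i, j], other)), collapse = "")
        }
      }
    }

    parts <- list()
    at <- 0L
    if (config$n_sites > 0L) {
      parts$GHR <- at + seq_len(config$n_sites)
      at <- at + config$n_sites
    }
    if (config$n_morph > 0L) {
      parts$morphology <- at + seq_len(config$n_morph)
      at <- at + config$n_morph
    }
    if (config$n_indel > 0L) {
      parts$indels <- at + seq_len(config$n_indel)
    }

    m <- char_matrix(cells, datatype = datatype, partitions = parts,
                     taxa = taxa)
    list(matrix = m, tree = tree)
  })
}

# simulate one block with phangorn::simSeq and return an upper-case character
# matrix (taxa x sites)
sim_phydat <- function(tree, l, type, levels = NULL, Q = NULL, bf = NULL,
                       rate = 1) {
  if (type == "DNA") {
    pd <- phangorn::simSeq(tree, l = l, type = "DNA", Q = Q, bf = bf,
                           rate = rate)
  } else {
    pd <- phangorn::simSeq(tree, l = l, type = "USER", levels = levels,
                           rate = rate)
  }
  out <- toupper(as.character(pd))
  rownames(out) <- names(pd)
  out[tree$tip.label, , drop = FALSE]
}

#' Frozen miniature mixed-matrix fixture
#'
#' A deterministic 9-taxon matrix shaped like a combined single-locus study
#' (three partitions, mixed datatypes, a few missing and polymorphic cells)
#' but small enough for exhaustive search. A copy generated with the default
#' seed ships with the package as `extdata/mixed_fixture.nex`.
#'
#' @param seed integer seed.
#' @return list with `matrix` and `tree`, as [simulate_matrix()].
#' @export
make_mixed_fixture <- function(seed = 42L) {
  cfg <- sim_config(
    n_taxa = 9, branch_length = 0.15, n_sites = 60, n_morph = 20,
    n_indel = 5, missing_fraction = 0.05, polymorphic_fraction = 0.02,
    gamma_shape = 0.8383
  )
  simulate_matrix(cfg, seed = seed)
}
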