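#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_hline labs
#'   scale_fill_manual coord_flip theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a branch-support table
#'
#' Bar chart of combined Bremer support, per-partition PBS and hidden branch
#' support per clade; negative PBS (partition conflict) shows below the axis.
#'
#' @param object a [build_support_table()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.support_table <- function(object, ...) {
  value_cols <- grep("(^bs$|_bs$|^hbs$)", names(object), value = TRUE)
  long <- tidyr::pivot_longer(
    dplyr::select(object, "clade", dplyr::all_of(value_cols)),
    -"clade", names_to = "component", values_to = "support"
  )
  long$component <- sub("_bs$", " PBS", long$component)
  long$component <- sub("^bs$", "combined BS", long$component)
  long$component <- sub("^hbs$", "HBS", long$component)
  ggplot(long, aes(x = .data$clade, y = .data$support,
                   fill = .data$component)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = "clade", y = "steps",
         title = "Branch support decomposition across partitions") +
    theme_minimal()
}

#' Plot a root survey
#'
#' Attachment counts per ingroup branch (largest first), with the unresolved
#' tally appended, visualizing where random outgroups are attracted.
#'
#' @param object a [survey_root()] result.
#' @param top show at most this many branches.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.root_survey <- function(object, top = 15, ...) {
  df <- utils::head(object$counts, top)
  df$branch <- vapply(strsplit(df$branch, ";", fixed = TRUE), function(s) {
    if (length(s) > 3L) paste0(s[1], " (+", length(s) - 1L, ")") else
      paste(s, collapse = "+")
  }, character(1))
  df <- dplyr::bind_rows(df, tibble(branch = "unresolved",
                                    count = object$unresolved_count))
  df$branch <- factor(df$branch, levels = rev(df$branch))
  ggplot(df, aes(x = .data$branch, y = .data$count)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = "attachment branch", y = "random outgroups",
         title = "Random-outgroup root attraction") +
    theme_minimal()
}

#' Plot bootstrap clade support
#'
#' @param tbl a [bootstrap_support()] tibble.
#' @param top show at most this many clades.
#' @return a ggplot.
#' @export
plot_bootstrap <- function(tbl, top = 20) {
  df <- utils::head(tbl, top)
  df$clade <- vapply(strsplit(df$clade, ";", fixed = TRUE), function(s) {
    if (length(s) > 3L) paste0(s[1], " (+", length(s) - 1L, ")") else
      paste(s, collapse = "+")
  }, character(1))
  df$clade <- factor(df$clade, levels = rev(unique(df$clade)))
  ggplot(df, aes(x = .data$clade, y = .data$support,
                 fill = .data$reported)) +
    geom_col() +
    geom_hline(yintercept = 50, linetype = 2) +
    scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70"),
                      name = "reported (>= 50)") +
    coord_flip() +
    labs(x = "clade", y = "bootstrap support (%)") +
    theme_minimal()
}

#' Plot the trees of a search result
#'
#' Base-graphics convenience: draws the strict consensus (or a chosen tree)
#' of an `mp_search`.
#'
#' @param x an `mp_search`.
#' @param which `"consensus"` or a tree index.
#' @param ... passed to [ape::plot.phylo()].
#' @return invisibly, the plotted tree.
#' @export
plot.mp_search <- function(x, which = "consensus", ...) {
  tr <- if (identical(which, "consensus") && length(x$trees) > 1L) {
    consensus_tree(x$trees, method = "strict")$tree
  } else if (identical(which, "consensus")) {
    x$trees[[1]]
  } else {
    x$trees[[as.integer(which)]]
  }
  plot(tr, ...)
  invisible(tr)
}

#' @importFrom rlang .data
NULL
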