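# ggplot2 views of the report tables.

#' Reads-per-unigene histogram
#'
#' Most unigenes in an EST survey carry only one to five reads; the
#' log-scaled count axis makes the long tail visible.
#'
#' @param unigenes Unigene tibble with `n_reads` (and optionally
#'   `species`).
#' @return A ggplot.
#' @export
plot_reads_per_unigene <- function(unigenes) {
  p <- ggplot2::ggplot(unigenes, ggplot2::aes(x = .data$n_reads)) +
    ggplot2::geom_bar() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "reads per unigene", y = "unigenes (log scale)")
  if ("species" %in% names(unigenes)) {
    p <- p + ggplot2::facet_wrap(~species)
  }
  p
}

#' Lineage category proportions
#'
#' @param lineage_summary Output of [summarize_lineages()], optionally
#'   with a `species` column.
#' @return A ggplot.
#' @export
plot_lineage_summary <- function(lineage_summary) {
  p <- ggplot2::ggplot(lineage_summary,
                       ggplot2::aes(x = .data$category,
                                    y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of unigenes") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if ("species" %in% names(lineage_summary)) {
    p <- p + ggplot2::facet_wrap(~species)
  }
  p
}

#' Venn-region gene counts
#'
#' @param venn Output of [venn_partition()].
#' @return A ggplot of per-region, per-species gene counts.
#' @export
plot_venn_counts <- function(venn) {
  ggplot2::ggplot(venn, ggplot2::aes(x = .data$region,
                                     y = .data$n_genes,
                                     fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "shared-ortholog region", y = "genes") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.go_enrichment <- function(object, ...) {
  long <- object |>
    select("namespace", "name", "stars", "prop_species",
           "prop_reference") |>
    tidyr::pivot_longer(c("prop_species", "prop_reference"),
                        names_to = "set", names_prefix = "prop_",
                        values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name,
                                     y = .data$proportion,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = distinct(long, .data$namespace, .data$name,
                      .data$stars) |>
        left_join(object |>
                    mutate(y = pmax(.data$prop_species,
                                    .data$prop_reference)) |>
                    select("namespace", "name", "y"),
                  by = c("namespace", "name")),
      ggplot2::aes(x = .data$name, y = .data$y, label = .data$stars),
      inherit.aes = FALSE, vjust = -0.3) +
    ggplot2::facet_wrap(~namespace, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "proportion of annotations") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
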