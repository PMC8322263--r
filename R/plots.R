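#' Plot a trait-pair overlap matrix
#'
#' Tile plot of the [trait_pair_matrix()]: upper triangle counts gene groups
#' with LD-independent cross-trait signals, lower triangle groups with
#' LD-dependent (shared) signals.
#'
#' @param object A `trait_pair_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trait_pair_matrix <- function(object, ...) {
  M <- unclass(object)
  df <- as_tibble(as.table(M), .name_repair = ~ c("trait_row", "trait_col",
                                                  "n")) %>%
    mutate(trait_row = factor(.data$trait_row, levels = rev(rownames(M))),
           trait_col = factor(.data$trait_col, levels = colnames(M)))
  ggplot2::ggplot(df, ggplot2::aes(.data$trait_col, .data$trait_row,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "groups",
                  title = "Cross-trait gene overlaps",
                  subtitle = "upper: LD-independent; lower: LD-dependent") +
    ggplot2::theme_minimal()
}

#' Plot per-trait Brown gene scores
#'
#' Scatter of -log10 Brown p-values by gene group, faceted by trait, with
#' an optional significance line.
#'
#' @param scores Output of [score_all_genes()] /
#'   [fdr_adjust_within_trait()].
#' @param threshold Optional p-value threshold drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_gene_scores <- function(scores, threshold = NULL) {
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(.data$group_id,
                                    -log10(.data$p_brown))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "gene group", y = expression(-log[10] * "(Brown p)")) +
    ggplot2::theme_bw()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot scenario counts across thresholds
#'
#' Bar chart of the [tabulate_scenarios()] table.
#'
#' @param scenario_table Output of [tabulate_scenarios()].
#' @return A ggplot.
#' @export
plot_scenario_counts <- function(scenario_table) {
  long <- scenario_table %>%
    tidyr::pivot_longer(-"scenario", names_to = "threshold",
                        values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(.data$scenario, .data$n,
                                     fill = .data$threshold)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "scenario", y = "gene groups") +
    ggplot2::theme_bw()
}
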