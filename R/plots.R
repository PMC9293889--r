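# ggplot2 visualisations of the main result types

#' Metagene profile along the 5'UTR / CDS / 3'UTR axis
#'
#' @param object an `m6a_metagene` tibble from [metagene_distribution()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot m6a_metagene
#' @export
autoplot.m6a_metagene <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_area(fill = "#2c7fb8", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(1, 2), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_continuous(
      breaks = c(0.5, 1.5, 2.5), labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = NULL, y = "peak density",
                  title = "m6A peak metagene distribution") +
    ggplot2::theme_minimal()
}

#' Cumulative half-life distributions of two conditions
#'
#' @param object a `halflife_comparison`.
#' @param cap_h half-life cap (hours) applied for display only; medians
#'   and tests are never affected. Default 24.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot halflife_comparison
#' @export
autoplot.halflife_comparison <- function(object, cap_h = 24, ...) {
  df <- bind_rows(
    tibble(condition = object$label_a,
           t_half = pmin(object$data$t_half_a, cap_h)),
    tibble(condition = object$label_b,
           t_half = pmin(object$data$t_half_b, cap_h))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_half,
                                   colour = .data$condition)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "half-life (h)", y = "cumulative fraction",
                  title = sprintf("median %s: %.2f h, %s: %.2f h (p = %.3g)",
                                  object$label_a, object$median_a,
                                  object$label_b, object$median_b,
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Decay curves for selected genes
#'
#' @param course long decay-course tibble.
#' @param genes gene ids to draw.
#' @return A ggplot of replicate-mean counts over time, log scale,
#'   faceted by gene and coloured by condition.
#' @export
plot_decay_curves <- function(course, genes) {
  df <- course %>%
    filter(.data$gene_id %in% genes) %>%
    group_by(.data$gene_id, .data$condition, .data$timepoint_h) %>%
    summarise(count = mean(.data$count), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint_h, y = .data$count,
                                   colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "time after transcription shutoff (h)",
                  y = "abundance (counts)") +
    ggplot2::theme_minimal()
}

#' Stacked peak-count bin fractions per stage
#'
#' @param bins result of [bin_genes_by_peak_count()].
#' @return A ggplot.
#' @export
plot_peak_bins <- function(bins) {
  df <- bins$summary
  if (!"stage" %in% names(df)) df$stage <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$fraction,
                                   fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of genes",
                  fill = "m6A peaks") +
    ggplot2::theme_minimal()
}

#' Volcano plot of per-transcript half-life changes
#'
#' @param changes tibble from [classify_halflife_changes()].
#' @return A ggplot of log2 half-life ratio against -log10 adjusted p.
#' @export
plot_halflife_volcano <- function(changes) {
  df <- changes %>% filter(is.finite(.data$ratio), !is.na(.data$padj))
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$ratio),
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(decreased = "#3182bd",
                                            increased = "#de2d26",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "log2 half-life ratio", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
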