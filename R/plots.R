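# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ideogram of a compartment fit
#'
#' One horizontal bar per chromosome, coloured by compartment segment.
#'
#' @param object A `compartment_fit` from [partition_genome()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot compartment_fit
#' @export
autoplot.compartment_fit <- function(object, ...) {
  seg <- object$segments
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start / 1e6, xmax = .data$end / 1e6,
      ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom), switch = "y") +
    ggplot2::scale_fill_manual(values = c(RR = "#b2182b", INT = "#fddbc7",
                                          RP = "#2166ac")) +
    ggplot2::labs(x = "position (Mb)", fill = "compartment", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
}

#' Windowed coverage profile
#'
#' Gene and repeat coverage along each chromosome, with optional compartment
#' shading.
#'
#' @param windows Output of [compute_window_coverage()] (or [tidy()] of a
#'   compartment fit).
#' @return A ggplot.
#' @export
plot_window_coverage <- function(windows) {
  long <- tidyr::pivot_longer(
    select(windows, "chrom", "start", "repeat_cov", "gene_cov"),
    c("repeat_cov", "gene_cov"), names_to = "track", values_to = "coverage")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start / 1e6,
                                     y = .data$coverage,
                                     colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::labs(x = "window start (Mb)", y = "coverage fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Fold-enrichment heatmap of consensus near differentially expressed genes
#'
#' Mirrors the up/down fold-bin tables: one tile per (consensus, status),
#' coloured by fold bin; only rows passing the filters are shown by default.
#'
#' @param enrichment Output of [consensus_de_enrichment()].
#' @param only_passing Show only filter-passing cells.
#' @return A ggplot.
#' @export
plot_consensus_enrichment <- function(enrichment, only_passing = TRUE) {
  d <- filter(enrichment, .data$status %in% c("up", "down"))
  if (only_passing) d <- filter(d, .data$passes_filters)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$status, y = .data$consensus_id,
                                  fill = .data$fold_bin)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(
      values = c("1-2.5" = "#ffff99", "2.5-6" = "#fdae61", "6-9" = "#d7191c"),
      na.value = "grey90", drop = FALSE) +
    ggplot2::labs(x = "regulation during ripening", y = "repeat consensus",
                  fill = "fold enrichment") +
    ggplot2::theme_minimal()
}
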