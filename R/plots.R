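# ggplot2 figures mirroring the standard Ribo-seq QC layouts: length
# spectrum, start/stop metagene, per-length periodicity heatmap, region
# stacked bars, codon ranking, occupancy scatter, and DE volcano.

#' Footprint length distribution barplot
#'
#' @param hist result of [length_histogram()].
#' @return A ggplot.
#' @export
plot_length_histogram <- function(hist) {
  ggplot2::ggplot(as_tibble(hist),
                  ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "footprint length (nt)", y = "reads",
                  title = "Footprint length distribution") +
    ggplot2::theme_minimal()
}

#' Metagene profile plot
#'
#' @param profile result of [metagene_profile()].
#' @return A ggplot; frame-0 positions are emphasized.
#' @export
plot_metagene <- function(profile) {
  df <- as_tibble(profile) %>%
    mutate(frame = factor(.data$position %% 3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                   fill = .data$frame)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = sprintf("nt from %s codon", attr(profile, "anchor")),
                  y = "P-site signal", fill = "frame") +
    ggplot2::theme_minimal()
}

#' Per-length periodicity heatmap
#'
#' @param heatmap result of [periodicity_heatmap()].
#' @return A ggplot tile map.
#' @export
plot_periodicity_heatmap <- function(heatmap) {
  ggplot2::ggplot(as_tibble(heatmap),
                  ggplot2::aes(x = .data$position,
                               y = factor(.data$read_length),
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = sprintf("nt from %s codon", attr(heatmap, "anchor")),
                  y = "read length (nt)", fill = "P-sites") +
    ggplot2::theme_minimal()
}

#' Observed vs expected region distribution
#'
#' @param regions result of [region_distribution()].
#' @return A ggplot of paired bars per region.
#' @export
plot_region_distribution <- function(regions) {
  df <- regions %>%
    tidyr::pivot_longer(c("observed", "expected"), names_to = "model",
                        values_to = "fraction") %>%
    mutate(region = factor(.data$region, levels = REGIONS,
                           labels = c("5'UTR", "CDS", "3'UTR")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$fraction,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "P-site fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Codon occupancy ranking plot
#'
#' Stop codons are marked with an asterisk; the start codon is highlighted.
#'
#' @param index a [codon_index()] table.
#' @param top number of codons shown from each end of the ranking (NULL =
#'   all defined codons).
#' @return A ggplot.
#' @export
plot_codon_ranking <- function(index, top = NULL) {
  df <- as_tibble(index) %>%
    filter(.data$defined) %>%
    arrange(.data$rank) %>%
    mutate(label = if_else(.data$is_stop, paste0(.data$codon, "*"),
                           .data$codon),
           class = dplyr::case_when(.data$codon == "AUG" ~ "start",
                                    .data$is_stop ~ "stop",
                                    TRUE ~ "sense"))
  if (!is.null(top)) df <- df[c(seq_len(top), nrow(df) - seq_len(top) + 1L), ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      -.data$index),
                                   y = .data$index, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(start = "dodgerblue",
                                          stop = "grey40",
                                          sense = "grey70")) +
    ggplot2::labs(x = NULL, y = "occupancy index",
                  title = sprintf("%s-site codon ranking",
                                  attr(index, "site"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Cross-condition occupancy scatter with outliers highlighted
#'
#' @param comparison result of [compare_occupancy()].
#' @return A ggplot; the Pearson r is annotated.
#' @export
plot_occupancy_comparison <- function(comparison) {
  df <- as_tibble(comparison)
  groups <- attr(comparison, "groups")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index_1, y = .data$index_2,
                                   color = .data$outlier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(data = df[df$outlier, ],
                       ggplot2::aes(label = .data$codon),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = sprintf("occupancy index (%s)", groups[1L] %||% "group 1"),
      y = sprintf("occupancy index (%s)", groups[2L] %||% "group 2"),
      title = sprintf("%s site, r = %.3f", attr(comparison, "site"),
                      attr(comparison, "pearson_r"))
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param de a [de_test()] result.
#' @return A ggplot.
#' @export
plot_volcano <- function(de) {
  df <- as_tibble(de)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$pvalue),
                                   color = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(up = "firebrick",
                                           down = "navy", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", color = NULL) +
    ggplot2::theme_minimal()
}
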