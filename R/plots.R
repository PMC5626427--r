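# ggplot2 views of the main result types.

#' Plot a sector map as a grid heatmap
#'
#' Fundus-view orientation: superior retina at the top, temporal at the left
#' (right-eye frame).
#'
#' @param x An `oct_sector_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oct_sector_map
#' @export
autoplot.oct_sector_map <- function(x, ...) {
  df <- as_tibble(x)
  df$sector <- factor(df$sector, levels = 7:11,
                      labels = paste(7:11, "o'clock"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$sector)) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_y_reverse(breaks = 1:10) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::scale_fill_viridis_d(na.value = "grey85",
                                  name = "cpRNFL sector") +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(x = "column (1 = temporal)", y = "row (1 = superior)",
                  title = "Axonal-tract-dependent macular sectors")
}

#' @rdname autoplot.oct_sector_map
#' @export
plot_sector_map <- function(x, ...) autoplot.oct_sector_map(x, ...)

#' Plot per-region slope distributions
#'
#' @param x An `oct_trend`.
#' @param ... Unused.
#' @return A ggplot object: one box per region and layer, with the normative
#'   reference location not drawn (slopes are already normative-compared in
#'   the table).
#' @method autoplot oct_trend
#' @export
autoplot.oct_trend <- function(x, ...) {
  df <- tidy(x)
  df$region <- factor(df$region, levels = REGIONS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(y = "slope (µm/year)", x = NULL,
                  title = "Per-eye progression slopes by region") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot VF/OCT agreement counts
#'
#' Bar-chart rendering of the Venn counts from [agreement()].
#'
#' @param agreement_table Output of [agreement()].
#' @return A ggplot object.
#' @export
plot_agreement <- function(agreement_table) {
  df <- agreement_table |>
    tidyr::pivot_longer(c("both", "vf_only", "oct_only", "neither"),
                        names_to = "cell", values_to = "count")
  df$cell <- factor(df$cell, levels = c("both", "vf_only", "oct_only",
                                        "neither"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::labs(x = NULL, y = "eyes",
                  title = "VF vs OCT progression agreement")
}
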