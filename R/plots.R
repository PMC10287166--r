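#' Plot a diel abundance series
#'
#' Points per replicate with a line through the timepoint means; vertical
#' shading marks the (18:00-06:00) night hours of each day.
#'
#' @param series Long tibble `contig_id`, `hours`, `value` (and optionally
#'   `replicate`), e.g. from [build_diel_series()].
#' @param contigs Optional subset of contig ids to show.
#' @return A ggplot object (facetted by contig).
#' @export
plot_diel_series <- function(series, contigs = NULL) {
  if (!is.null(contigs))
    series <- series[series$contig_id %in% contigs, ]
  means <- series |>
    dplyr::group_by(.data$contig_id, .data$hours) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  nights <- tibble::tibble(
    xmin = seq(-6, max(series$hours), by = 24),
    xmax = seq(6, max(series$hours) + 12, by = 24))
  nights$xmin <- pmax(nights$xmin, 0)
  nights$xmax <- pmin(nights$xmax, max(series$hours))
  ggplot2::ggplot(series, ggplot2::aes(x = .data$hours, y = .data$value)) +
    ggplot2::geom_rect(data = nights,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "grey85", alpha = 0.5) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = means, linewidth = 0.4) +
    ggplot2::facet_wrap(~contig_id, scales = "free_y") +
    ggplot2::labs(x = "hours since start", y = "abundance (reads/L)") +
    ggplot2::theme_minimal()
}

#' Histogram of significant peak phases
#'
#' @param object Tibble from [detect_rhythms()].
#' @param q_max Significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rhythm_tbl
#' @export
autoplot.rhythm_tbl <- function(object, q_max = 0.05, ...) {
  ph <- summarize_phases(object, q_max = q_max)
  ggplot2::ggplot(ph, ggplot2::aes(x = factor(.data$phase),
                                   y = .data$n_significant)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "peak phase (hours, time of day)",
                  y = "significant contigs",
                  title = sprintf("%d of %d contigs rhythmic (q < %g)",
                                  attr(ph, "n_significant"),
                                  attr(ph, "n_tested"), q_max)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of combined clade x genus abundances
#'
#' @param combined Tibble from [combine_samples()] (`clade`, `genus`,
#'   `station`, `value`).
#' @return A ggplot object.
#' @export
plot_clade_heatmap <- function(combined) {
  ggplot2::ggplot(combined,
                  ggplot2::aes(x = .data$station,
                               y = paste(.data$clade, .data$genus, sep = " / "),
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "order fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
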