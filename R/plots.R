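#' Plot paired pattern proportions
#'
#' Side-by-side bars of each rater's longitudinal-pattern percentages, one
#' panel per context — the standard headline figure for a paired-rater
#' consistency comparison.
#'
#' @param analysis A [run_density_analysis()] result, or a pattern-table
#'   tibble with columns `context`, `rater`, `pattern`, `pct`.
#' @param subgroup Which subgroup to plot (default `"full"`).
#' @return A ggplot object.
#' @export
plot_pattern_proportions <- function(analysis, subgroup = "full") {
  df <- if (inherits(analysis, "density_analysis")) {
    dplyr::filter(analysis$pattern_tables, .data$subgroup == !!subgroup)
  } else {
    tibble::as_tibble(analysis)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$pct,
                                   fill = .data$rater)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::facet_wrap(~context) +
    ggplot2::labs(x = "longitudinal density pattern", y = "% of women",
                  fill = "rater") +
    ggplot2::theme_minimal()
}

#' Heatmap of the paired pattern cross-tabulation
#'
#' @param paired A [paired_pattern_table()] tibble.
#' @return A ggplot object: AI pattern on rows, radiologist pattern on
#'   columns, cell fill and label by count.
#' @export
plot_paired_patterns <- function(paired) {
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$reader_pattern,
                                       y = .data$ai_pattern,
                                       fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "radiologist pattern", y = "AI pattern", fill = "women") +
    ggplot2::theme_minimal()
}

#' First-to-last density transition plot
#'
#' Segment-based flow rendering of a [transition_table()] (a Sankey without
#' external dependencies): line width encodes the number of women moving
#' from their first-exam to last-exam category.
#'
#' @param transitions A [transition_table()] tibble.
#' @return A ggplot object.
#' @export
plot_transitions <- function(transitions) {
  df <- dplyr::filter(transitions, .data$n > 0)
  df$first_num <- as.integer(factor(df$first_density, levels = density_levels))
  df$last_num <- as.integer(factor(df$last_density, levels = density_levels))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = 1, y = .data$first_num, yend = .data$last_num,
                   linewidth = .data$n, colour = .data$first_density),
      alpha = 0.6
    ) +
    ggplot2::scale_y_continuous(breaks = 1:4, labels = density_levels) +
    ggplot2::scale_x_continuous(breaks = c(0, 1),
                                labels = c("first exam", "last exam")) +
    ggplot2::labs(y = "BI-RADS density", x = NULL, linewidth = "women",
                  colour = "first category") +
    ggplot2::theme_minimal()
}
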