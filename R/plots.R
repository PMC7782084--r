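# Figures: per-cohort size and NCR distributions, summary dot plots, and
# the comparison p-value panel.

cohort_label <- function(group, material) {
  if_else(material == "blood" | is.na(material), group,
          paste0(group, " (", material, ")"))
}

#' Plot per-cohort cell size distributions
#'
#' Violin + box plot of the cell-signal area per cohort on a log scale,
#' the per-cohort analogue of the study's size figure.
#'
#' @param morph Morphometry tibble ([morphometry_table()]).
#' @param value Data-masked column to plot (default `cell_area`).
#' @return A ggplot object.
#' @export
plot_size_distributions <- function(morph, value = cell_area) {
  morph <- as_tibble(morph) |>
    mutate(cohort = cohort_label(.data$group, .data$material))
  ggplot2::ggplot(morph, ggplot2::aes(x = .data$cohort, y = {{ value }})) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = expression("Cell size (" * mu * m^2 * ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot per-cohort nucleus/cytoplasm ratio distributions
#'
#' @inheritParams plot_size_distributions
#' @return A ggplot object.
#' @export
plot_ncr_distributions <- function(morph) {
  morph <- as_tibble(morph) |>
    filter(!is.na(.data$ncr)) |>
    mutate(cohort = cohort_label(.data$group, .data$material))
  ggplot2::ggplot(morph, ggplot2::aes(x = .data$cohort, y = .data$ncr)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Nucleus/cytoplasm ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.ctc_cohort_summary <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(cohort = cohort_label(.data$group, .data$material))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cohort, y = .data$median_area)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$median_area - .data$iqr_area / 2, 0),
      ymax = .data$median_area + .data$iqr_area / 2)) +
    ggplot2::labs(x = NULL, y = expression("Median cell size (" * mu * m^2 * ")"),
                  caption = "bars: half the interquartile width each side") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.ctc_comparisons <- function(object, alpha = 0.05, ...) {
  d <- as_tibble(object) |>
    mutate(neglog = -log10(pmax(.data$p_value, 1e-16)),
           significant = .data$p_value < alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, .data$neglog),
                                  y = .data$neglog, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey30", `FALSE` = "grey75"),
                               name = sprintf("p < %g", alpha)) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @export
tidy.ctc_comparisons <- function(x, ...) {
  as_tibble(x) |>
    select(all_of(intersect(c("label", "test", "groups", "statistic", "df",
                              "p_value", "p_adjusted", "note"), names(x)))) |>
    mutate(p_formatted = format_p(.data$p_value))
}

#' @export
glance.ctc_comparisons <- function(x, alpha = 0.05, ...) {
  tibble(n_tests = nrow(x),
         n_significant = sum(x$p_value < alpha, na.rm = TRUE),
         min_p = if (nrow(x)) min(x$p_value, na.rm = TRUE) else NA_real_,
         alpha = alpha)
}

#' @export
tidy.ctc_cohort_summary <- function(x, ...) as_tibble(x)

#' @export
glance.ctc_cohort_summary <- function(x, ...) {
  tibble(n_cohorts = nrow(x), n_events = sum(x$n),
         n_nucleus_events = sum(x$n_nucleus, na.rm = TRUE))
}
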