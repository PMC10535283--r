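# Optional figures: diverging percentage-point bar charts of ratio
# comparisons and box-and-whisker plots of the count distributions.

#' Diverging bar chart of percentage-point differences
#'
#' Horizontal bars of the statistically significant percentage-point
#' differences in a ratio comparison, colour-coded by direction (items
#' reported more often by non-HPs extend right, by HPs left).
#'
#' @param comparison A tibble from [compare_ratios()].
#' @param significant_only Keep only significant rows (default `TRUE`).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_ratio_comparison <- function(comparison, significant_only = TRUE,
                                  title = NULL) {
  df <- if (significant_only) {
    comparison[comparison$significant, , drop = FALSE]
  } else comparison
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = title %||% "no significant differences"))
  }
  df$direction <- ifelse(df$pp_diff > 0, "non-HP", "HP")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pp_diff,
    y = stats::reorder(.data$item, abs(.data$pp_diff)),
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c("non-HP" = "#4477AA", "HP" = "#228833"),
      name = "more often reported by"
    ) +
    ggplot2::labs(x = "difference in reporting ratio (percentage points)",
                  y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plots of the count variables by reporter group
#'
#' One panel per count variable, with the mean marked by a white point.
#'
#' @param cohort An `icsr_cohort`.
#' @return A ggplot object.
#' @export
plot_count_distributions <- function(cohort) {
  counts <- case_counts(cohort)
  long <- tidyr::pivot_longer(counts, dplyr::all_of(COUNT_VARIABLES),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$reporter_group,
                                     y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 21,
                          fill = "white", size = 2.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "count per case") +
    ggplot2::theme_minimal()
}
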