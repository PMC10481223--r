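#' Plot a normative reference chart
#'
#' MM% against day postpartum with the percentile lines drawn in the
#' conventional styles: solid for the lowest level, dashed for the median,
#' dot-dash for the highest.
#'
#' @param object A `reference_chart`.
#' @param max_day Truncate the x axis (default 60; the open-ended last bin
#'   is drawn at its start).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reference_chart
#' @export
autoplot.reference_chart <- function(object, max_day = 60, ...) {
  long <- tidy(object)
  long$day <- ifelse(is.finite(long$bin_end),
                     (long$bin_start + long$bin_end) / 2, long$bin_start)
  long <- long[long$day <= max_day & !is.na(long$mm_percent), , drop = FALSE]
  long$level <- factor(paste0("p", long$level))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$mm_percent,
                                     linetype = .data$level)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = stats::setNames(c("solid", "dashed", "dotdash")[
        seq_len(nlevels(long$level))], levels(long$level))) +
    ggplot2::labs(x = "Day postpartum", y = "MM%",
                  linetype = "Percentile") +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}

#' Plot per-range class means with standard errors
#'
#' @param object A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$day_range,
                                      y = .data$mean_mm,
                                      colour = .data$class_label,
                                      group = .data$class_label)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_mm - .data$se_mm,
                   ymax = .data$mean_mm + .data$se_mm),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "Day range postpartum", y = "Mean MM% (+/- SE)",
                  colour = "Class")
}

#' Plot individual MM% trajectories against the reference lines
#'
#' Per-breast scan series for one or more mothers, overlaid on the
#' reference chart's threshold and median lines.
#'
#' @param records Scan records with `mother_id`, `breast_side`,
#'   `day_postpartum`, `mm_percent`.
#' @param chart Optional `reference_chart` whose p15/p50 lines are drawn in
#'   black.
#' @param max_day X-axis limit in days.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(records, chart = NULL, max_day = 30) {
  p <- ggplot2::ggplot(
    records[records$day_postpartum <= max_day, , drop = FALSE],
    ggplot2::aes(x = .data$day_postpartum, y = .data$mm_percent,
                 colour = .data$mother_id, linetype = .data$breast_side)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Day postpartum", y = "MM%",
                  colour = "Mother", linetype = "Breast") +
    ggplot2::coord_cartesian(ylim = c(0, 100))
  if (!is.null(chart)) {
    long <- tidy(chart)
    long$day <- ifelse(is.finite(long$bin_end),
                       (long$bin_start + long$bin_end) / 2, long$bin_start)
    long <- long[long$level %in% c(15, 50) & long$day <= max_day &
                   !is.na(long$mm_percent), , drop = FALSE]
    p <- p + ggplot2::geom_line(
      data = long,
      ggplot2::aes(x = .data$day, y = .data$mm_percent,
                   group = .data$level),
      colour = "black", linetype = "solid",
      inherit.aes = FALSE, alpha = 0.7)
  }
  p
}
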