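#' Plot the total-score distribution over the attainable range
#'
#' Histogram of totals binned by [score_histogram()], filled on a
#' green-to-red gradient across the instrument's possible range so that
#' high-priority (low-scoring) cases read green and deferrable (high-scoring)
#' cases read red.
#'
#' @param sheets Score sheets.
#' @param binwidth Bin width in score points (default 1).
#' @param range Attainable total range, default `c(16, 80)`.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(sheets, binwidth = 1L, range = c(16L, 80L)) {
  bins <- score_histogram(sheets, binwidth = binwidth, range = range)
  bins$mid <- (bins$bin_lower + bins$bin_upper) / 2
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mid, y = .data$count,
                                     fill = .data$mid)) +
    ggplot2::geom_col(width = binwidth) +
    ggplot2::scale_fill_gradient2(low = "#1a9850", mid = "#fee08b",
                                  high = "#d73027",
                                  midpoint = mean(range), limits = range,
                                  guide = "none") +
    ggplot2::labs(x = "Total score (lower = higher priority)", y = "Cases") +
    ggplot2::theme_minimal()
}

#' Plot group score summaries as median points with ranges
#'
#' @param summaries Output of [summarize_scores()].
#' @param measure One of `"total"`, `"procedure_subtotal"`,
#'   `"disease_subtotal"`, `"patient_subtotal"`.
#' @return A ggplot object.
#' @export
plot_group_summaries <- function(summaries, measure = "total") {
  med <- paste0(measure, "_median")
  lo <- paste0(measure, "_min")
  hi <- paste0(measure, "_max")
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$group, y = .data[[med]])) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[[lo]],
                                          ymax = .data[[hi]])) +
    ggplot2::labs(x = NULL, y = paste0(measure, " (median and range)")) +
    ggplot2::theme_minimal()
}

#' @rdname tier_crosswalk
#' @param object A `ments_crosswalk`.
#' @param ... Unused.
#' @export
autoplot.ments_crosswalk <- function(object, ...) {
  plot_group_summaries(object$summary) +
    ggplot2::labs(x = "Acuity tier",
                  subtitle = if (object$monotone) {
                    "Tier medians monotone (high <= intermediate <= low)"
                  } else "Tier medians not monotone")
}
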