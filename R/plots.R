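type_palette <- function() {
  c(regular_pro = "#1f78b4", express_pro = "#00bcd4",
    correct_anti = "#e31a1c", regular_error = "#8c510a",
    express_error = "#ff7f00", anticipatory = "grey60",
    no_response = "grey30", pro_error = "grey45")
}

#' Plot reaction-time histograms
#'
#' Instantaneous (or cumulative) SRT histograms for the five saccade types,
#' with direction errors drawn below the zero line and the express window
#' shaded, in the style used to present this behaviour.
#'
#' @param records Classified trial records.
#' @param bin_ms Bin width in ms (default 6).
#' @param cumulative Plot cumulative curves instead of instantaneous bars.
#' @param windows A [saccade_windows()] (for the shaded express window).
#' @return A ggplot object.
#' @export
plot_srt_histogram <- function(records, bin_ms = 6, cumulative = FALSE,
                               windows = saccade_windows()) {
  h <- srt_histogram(records, bin_ms)
  h <- h[h$saccade_type %in% saccade_types(), ]
  err <- c("regular_error", "express_error")
  h$y <- if (cumulative) h$cum_pct else h$pct
  h$y <- ifelse(h$saccade_type %in% err, -h$y, h$y)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start, y = .data$y,
                                  colour = .data$saccade_type)) +
    ggplot2::annotate("rect", xmin = windows$express_lo,
                      xmax = windows$express_hi, ymin = -Inf, ymax = Inf,
                      fill = "grey85", alpha = 0.6) +
    ggplot2::geom_step(linewidth = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_colour_manual(values = type_palette(), name = NULL) +
    ggplot2::labs(x = "SRT (ms)",
                  y = if (cumulative) "cumulative % of task trials"
                      else "% of task trials") +
    ggplot2::theme_minimal()
}

#' Plot the anti-saccade difference curve
#'
#' Cumulative percent correct minus cumulative percent error over time, with
#' the voluntary override time marked when defined.
#'
#' @param curve An [anti_difference_curve()].
#' @return A ggplot object.
#' @export
plot_difference_curve <- function(curve) {
  vot <- voluntary_override_time(curve)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#e31a1c") +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = "cumulative % correct - % error") +
    ggplot2::theme_minimal()
  if (!is.na(vot)) {
    p <- p + ggplot2::geom_vline(xintercept = vot, linetype = 2,
                                 colour = "grey30")
  }
  p
}

#' Plot level proportions behind saccade selection
#'
#' Stacked setting proportions per attribute and saccade type from
#' [selection_effects()]; attributes whose proportions depart from uniform
#' thirds reveal settings that caused or blocked a behaviour.
#'
#' @param effects A [selection_effects()] table.
#' @return A ggplot object.
#' @export
plot_selection_effects <- function(effects) {
  long <- tidyr::pivot_longer(
    effects, c("n_small", "n_medium", "n_large"),
    names_to = "level", names_prefix = "n_", values_to = "n"
  )
  long$level <- factor(long$level, levels = c("small", "medium", "large"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$attribute, y = .data$n,
                                     fill = .data$level)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::geom_hline(yintercept = c(1, 2) / 3, linetype = 3,
                        colour = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$saccade_type)) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_brewer(palette = "Blues") +
    ggplot2::labs(x = NULL, y = "proportion of trials") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_srt_histogram Autoplot method for `saccade_sim` objects.
#' @param object A `saccade_sim`.
#' @param ... Passed to [plot_srt_histogram()].
#' @export
autoplot.saccade_sim <- function(object, ...) {
  plot_srt_histogram(object$records, ...)
}
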