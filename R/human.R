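#' Published human reference behaviour
#'
#' Summary statistics of the pro- and anti-saccade behaviour of 74 healthy
#' adult participants (ages 18-39) in the gap paradigm, shipped as read-only
#' constants for side-by-side reporting against the model. Counts are totals
#' over the population; percentages and SRT statistics are participant
#' averages.
#'
#' @return Tibble with one row per saccade type: `saccade_type`, `task`,
#'   `total_count`, `mean_count`, `percent`, `median_srt`, `mean_srt`,
#'   `sd_srt`.
#' @export
human_reference <- function() {
  tibble::tibble(
    saccade_type = saccade_types(),
    task = c("pro", "pro", "anti", "anti", "anti"),
    total_count = c(4502, 818, 8171, 390, 259),
    mean_count = c(61.7, 11.2, 110.4, 5.3, 3.5),
    percent = c(86.6, 13.4, 92.3, 4.7, 3.0),
    median_srt = c(206.3, 120.0, 253.6, 212.9, 117.6),
    mean_srt = c(213.8, 119.3, 259.9, 226.7, 117.4),
    sd_srt = c(42.0, 10.7, 50.1, 63.6, 10.0)
  )
}

#' Reference human voluntary override time
#'
#' The published average voluntary override time of the human population,
#' for comparison with the model's value.
#'
#' @return Time in ms.
#' @export
human_override_time <- function() 168

#' Compare a model summary with the human reference
#'
#' Side-by-side table of percentages and SRT statistics for the five saccade
#' types, with model-minus-human differences. No inferential tests are run
#' (raw human data are not available), this is descriptive reporting only.
#'
#' @param model_summary A [summarize_behavior()] table.
#' @param human A [human_reference()]-shaped table.
#' @return Tibble with one row per saccade type and `*_model`, `*_human` and
#'   `*_diff` columns for percent, median and mean SRT.
#' @export
compare_to_human <- function(model_summary, human = human_reference()) {
  m <- model_summary[model_summary$saccade_type %in% saccade_types(),
                     c("saccade_type", "percent", "median_srt", "mean_srt")]
  h <- human[, c("saccade_type", "percent", "median_srt", "mean_srt")]
  out <- dplyr::inner_join(m, h, by = "saccade_type",
                           suffix = c("_model", "_human"))
  out |>
    dplyr::mutate(
      percent_diff = .data$percent_model - .data$percent_human,
      median_srt_diff = .data$median_srt_model - .data$median_srt_human,
      mean_srt_diff = .data$mean_srt_model - .data$mean_srt_human
    )
}
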