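#' Tidy a simulated experiment
#'
#' Returns the classified per-trial records of a [simulate_experiment()]
#' run, one row per trial.
#'
#' @param x A `saccade_sim` object.
#' @param ... Unused.
#' @return A tibble of trial records.
#' @export
tidy.saccade_sim <- function(x, ...) {
  tibble::as_tibble(x$records)
}

#' One-row glance at a simulated experiment
#'
#' Headline numbers of a run: trial count, per-type percentages, the
#' regular-latency medians, and the voluntary override time when anti-task
#' trials are present.
#'
#' @param x A `saccade_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.saccade_sim <- function(x, ...) {
  s <- x$summary
  val <- function(col, type) {
    v <- s[[col]][s$saccade_type == type]
    if (length(v)) v else NA_real_
  }
  vot <- if (any(x$records$task == "anti")) {
    voluntary_override_time(anti_difference_curve(x$records))
  } else {
    NA_real_
  }
  tibble::tibble(
    n_trials = nrow(x$records),
    pct_express_pro = val("percent", "express_pro"),
    pct_express_error = val("percent", "express_error"),
    pct_regular_error = val("percent", "regular_error"),
    median_regular_pro = val("median_srt", "regular_pro"),
    median_correct_anti = val("median_srt", "correct_anti"),
    median_regular_error = val("median_srt", "regular_error"),
    override_time = vot
  )
}
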