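#' Saccade classification windows
#'
#' Latency windows used to classify saccades: anything initiated before
#' 90 ms is anticipatory (equally likely in either direction, excluded from
#' the five behavioural types); express latency saccades are initiated
#' between 90 and 138 ms inclusive (138 is a multiple of the 6-ms histogram
#' bin and closest to the conventional 140 ms, and is kept inside the express
#' window); later saccades are regular latency.
#'
#' @param anticipatory_max Lower edge of the express window / exclusive upper
#'   bound for anticipatory saccades (default 90 ms).
#' @param express_hi Inclusive upper edge of the express window (default 138 ms).
#' @param regular_hi End of the simulation window (default 600 ms).
#' @param express_inclusive Whether both window edges count as express
#'   (default `TRUE`).
#' @return Named list of class `saccade_windows`.
#' @export
saccade_windows <- function(anticipatory_max = 90, express_hi = 138,
                            regular_hi = 600, express_inclusive = TRUE) {
  stopifnot(anticipatory_max < express_hi, express_hi < regular_hi)
  structure(
    list(anticipatory_max = anticipatory_max, express_lo = anticipatory_max,
         express_hi = express_hi, regular_hi = regular_hi,
         express_inclusive = express_inclusive),
    class = "saccade_windows"
  )
}

#' The five saccade types
#'
#' Level order used throughout the package's tables and plots.
#'
#' @return Character vector of the five type labels.
#' @export
saccade_types <- function() {
  c("regular_pro", "express_pro", "correct_anti", "regular_error",
    "express_error")
}

#' Classify saccades into the five behavioural types
#'
#' Pure, vectorised mapping from (task, stimulus side, saccade direction,
#' latency) to the behavioural taxonomy: saccades before 90 ms are
#' anticipatory; pro-saccades towards the stimulus are express or regular
#' correct pro-saccades; anti-saccades away from the stimulus are correct
#' anti-saccades (no express/regular split); anti-saccades towards the
#' stimulus are express or regular direction errors. A pro-task saccade away
#' from the stimulus (never produced by the baseline model) is labelled
#' `pro_error` and excluded from the five-type tables. Missing latency means
#' no saccade was triggered (`no_response`).
#'
#' @param task `"pro"` or `"anti"` (vectorised).
#' @param stimulus_side `"left"` or `"right"` (vectorised).
#' @param direction Saccade direction, `"left"`, `"right"` or `NA`.
#' @param srt Saccadic reaction time in ms (NA if no saccade).
#' @param windows A [saccade_windows()] object.
#' @return Character vector of types.
#' @examples
#' classify_saccade("pro", "right", "right", 120) # express_pro
#' classify_saccade("anti", "right", "right", 186) # regular_error
#' @export
classify_saccade <- function(task, stimulus_side, direction, srt,
                             windows = saccade_windows()) {
  n <- max(length(task), length(stimulus_side), length(direction), length(srt))
  task <- rep_len(task, n); stimulus_side <- rep_len(stimulus_side, n)
  direction <- rep_len(direction, n); srt <- rep_len(srt, n)
  express <- if (windows$express_inclusive) {
    srt >= windows$express_lo & srt <= windows$express_hi
  } else {
    srt > windows$express_lo & srt < windows$express_hi
  }
  toward <- direction == stimulus_side
  out <- character(n)
  out[is.na(srt)] <- "no_response"
  ok <- !is.na(srt)
  anticip <- ok & srt < windows$anticipatory_max
  out[anticip] <- "anticipatory"
  rest <- ok & !anticip
  out[rest & task == "pro" & toward & express] <- "express_pro"
  out[rest & task == "pro" & toward & !express] <- "regular_pro"
  out[rest & task == "pro" & !toward] <- "pro_error"
  out[rest & task == "anti" & !toward] <- "correct_anti"
  out[rest & task == "anti" & toward & express] <- "express_error"
  out[rest & task == "anti" & toward & !express] <- "regular_error"
  out
}
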