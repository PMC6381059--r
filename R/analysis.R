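#' Sample skewness (adjusted Fisher-Pearson)
#'
#' The adjusted Fisher-Pearson standardised third moment,
#' `n / ((n-1)(n-2)) * sum(((x - mean) / s)^3)` with `s` the sample (n-1)
#' standard deviation.
#'
#' @param x Numeric vector.
#' @return The skewness, or `NA` for fewer than three values or zero spread.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(NA_real_)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

#' Behavioural summary table
#'
#' Per-task, per-type counts, percentages and reaction-time statistics: the
#' machine twin of the model's behavioural data table. Percentages use the
#' task's trial count as denominator, so the pro types and the anti types
#' each sum to 100 (up to excluded anticipatory/no-response trials, absent
#' in the baseline model).
#'
#' @param records Classified trial records from [run_trials()].
#' @return A tibble with columns `saccade_type`, `task`, `count`, `percent`,
#'   `median_srt`, `mean_srt`, `sd_srt`, `skewness`.
#' @export
summarize_behavior <- function(records) {
  if (nrow(records) == 0) stop("no records to summarise")
  task_n <- dplyr::count(records, .data$task, name = "task_total")
  out <- records |>
    dplyr::group_by(.data$task, .data$saccade_type) |>
    dplyr::summarise(
      count = dplyr::n(),
      median_srt = stats::median(.data$srt),
      mean_srt = mean(.data$srt),
      sd_srt = dplyr::if_else(dplyr::n() > 1, stats::sd(.data$srt), 0),
      skewness = sample_skewness(.data$srt),
      .groups = "drop"
    ) |>
    dplyr::left_join(task_n, by = "task") |>
    dplyr::mutate(percent = 100 * .data$count / .data$task_total) |>
    dplyr::select("saccade_type", "task", "count", "percent",
                  "median_srt", "mean_srt", "sd_srt", "skewness")
  ord <- c(saccade_types(), "anticipatory", "no_response", "pro_error")
  out[order(match(out$saccade_type, ord)), ]
}

#' Reaction-time histograms
#'
#' Instantaneous and cumulative SRT histograms per saccade type using 6-ms
#' bins aligned at stimulus onset. Bins are labelled by their left edge and
#' are left-closed (`bin_start <= srt < bin_start + bin_ms`); percentages
#' use the task's trial count, so a type's cumulative curve converges to its
#' percentage in the summary table.
#'
#' @param records Classified trial records.
#' @param bin_ms Bin width in ms (default 6).
#' @return Tibble with `saccade_type`, `task`, `bin_start`, `count`, `pct`
#'   and `cum_pct`, with empty bins kept so curves are complete.
#' @export
srt_histogram <- function(records, bin_ms = 6) {
  stopifnot(bin_ms > 0)
  records <- records[!is.na(records$srt), ]
  task_n <- dplyr::count(records, .data$task, name = "task_total")
  lo <- min(0, floor(min(records$srt) / bin_ms) * bin_ms)
  hi <- floor(max(records$srt) / bin_ms) * bin_ms
  bins <- seq(lo, hi, by = bin_ms)
  counts <- records |>
    dplyr::mutate(bin_start = floor(.data$srt / bin_ms) * bin_ms) |>
    dplyr::count(.data$task, .data$saccade_type, .data$bin_start)
  tidyr::crossing(dplyr::distinct(counts, .data$task, .data$saccade_type),
                  bin_start = bins) |>
    dplyr::left_join(counts, by = c("task", "saccade_type", "bin_start")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::left_join(task_n, by = "task") |>
    dplyr::group_by(.data$task, .data$saccade_type) |>
    dplyr::arrange(.data$bin_start, .by_group = TRUE) |>
    dplyr::mutate(count = .data$n,
                  pct = 100 * .data$count / .data$task_total,
                  cum_pct = cumsum(.data$pct)) |>
    dplyr::ungroup() |>
    dplyr::select("saccade_type", "task", "bin_start", "count", "pct",
                  "cum_pct")
}

behavior_subset <- function(records, behavior) {
  r <- records[records$saccade_type == behavior, ]
  if (nrow(r) == 0) stop("no records for behaviour: ", behavior)
  r
}

#' Median SRT shift between the large and small setting
#'
#' The absolute-effect measure: the difference in median SRT between the
#' trials with the large and the small setting of one varied attribute,
#' within one behaviour's records.
#'
#' @param records Classified trial records.
#' @param attribute One of the ten varied attribute codes (see
#'   [varied_attributes()]).
#' @param behavior A saccade type (default the three regular-latency
#'   behaviours used in the effect tables).
#' @return Tibble with `attribute`, `behavior` and `median_shift` (ms).
#' @export
median_shift <- function(records, attribute,
                         behavior = c("regular_pro", "correct_anti",
                                      "regular_error")) {
  stopifnot(attribute %in% names(attribute_levels()))
  lv_col <- paste0(attribute, "_level")
  purrr::map_dfr(behavior, function(bh) {
    r <- behavior_subset(records, bh)
    lv <- r[[lv_col]]
    if (!any(lv == "small") || !any(lv == "large")) {
      stop("empty level subgroup for ", attribute, " in ", bh)
    }
    tibble::tibble(
      attribute = attribute, behavior = bh,
      median_shift = stats::median(r$srt[lv == "large"]) -
        stats::median(r$srt[lv == "small"])
    )
  })
}

#' Cohen's d from a median shift
#'
#' Effect size normalised by the behaviour's full SRT standard deviation:
#' `d = median_shift / behavior_sd`.
#'
#' @param median_shift Median shift in ms.
#' @param behavior_sd Standard deviation of the behaviour's full SRT
#'   distribution (must be positive).
#' @return The effect size.
#' @export
cohens_d <- function(median_shift, behavior_sd) {
  stopifnot(all(behavior_sd > 0))
  median_shift / behavior_sd
}

#' Kruskal-Wallis test across setting subgroups
#'
#' Standard rank-based H with tie correction and the chi-square p
#' approximation. Degenerate input (all values identical across all groups)
#' yields `H = 0`, `p = 1`.
#'
#' @param groups List of numeric vectors (at least two non-empty).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least two non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Attribute effects on reaction time
#'
#' For each varied attribute and each of the regular-latency behaviours:
#' the large-minus-small median SRT shift, Cohen's d against the behaviour's
#' overall SRT standard deviation, and the Kruskal-Wallis test across the
#' three setting subgroups (the twins of the published effect tables).
#'
#' @param records Classified trial records.
#' @param attributes Attribute codes (default all ten).
#' @param behaviors Behaviours analysed (default the three regular-latency
#'   ones).
#' @return Tibble with one row per attribute x behaviour.
#' @export
attribute_effects <- function(records,
                              attributes = names(attribute_levels()),
                              behaviors = c("regular_pro", "correct_anti",
                                            "regular_error")) {
  sds <- purrr::map_dbl(
    stats::setNames(behaviors, behaviors),
    function(bh) stats::sd(behavior_subset(records, bh)$srt)
  )
  purrr::map_dfr(attributes, function(attr) {
    lv_col <- paste0(attr, "_level")
    purrr::map_dfr(behaviors, function(bh) {
      r <- behavior_subset(records, bh)
      shift <- median_shift(records, attr, bh)$median_shift
      kw <- kruskal_wallis(split(r$srt, r[[lv_col]]))
      tibble::tibble(
        attribute = attr, behavior = bh, median_shift = shift,
        behavior_sd = sds[[bh]],
        cohens_d = cohens_d(shift, sds[[bh]]),
        kruskal_h = kw$H, kruskal_p = kw$p
      )
    })
  })
}

#' Chi-square test of setting proportions within a saccade type
#'
#' Goodness-of-fit of the observed small/medium/large counts of one
#' attribute, among the trials yielding one saccade type, against the
#' expected uniform thirds. A significant result means the setting helped
#' cause (or block) that behaviour.
#'
#' @param records Classified trial records.
#' @param attribute A varied attribute code.
#' @param saccade_type One of the five saccade types.
#' @return List with `chi2`, `p`, and `level_counts` (named small/medium/
#'   large).
#' @export
selection_chi_square <- function(records, attribute, saccade_type) {
  stopifnot(attribute %in% names(attribute_levels()))
  r <- behavior_subset(records, saccade_type)
  lv <- factor(r[[paste0(attribute, "_level")]],
               levels = c("small", "medium", "large"))
  counts <- table(lv)
  expected <- length(lv) / 3
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 2, lower.tail = FALSE),
       level_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Setting proportions behind saccade selection
#'
#' [selection_chi_square()] over all varied attributes and saccade types
#' present in the records (the twin of the published selection analysis).
#'
#' @param records Classified trial records.
#' @param attributes Attribute codes (default all ten).
#' @param types Saccade types (default the five present in the records).
#' @return Tibble with one row per attribute x type, including the level
#'   counts.
#' @export
selection_effects <- function(records,
                              attributes = names(attribute_levels()),
                              types = intersect(saccade_types(),
                                                unique(records$saccade_type))) {
  purrr::map_dfr(attributes, function(attr) {
    purrr::map_dfr(types, function(tp) {
      cs <- selection_chi_square(records, attr, tp)
      tibble::tibble(
        attribute = attr, saccade_type = tp, chi2 = cs$chi2, p = cs$p,
        n_small = cs$level_counts[["small"]],
        n_medium = cs$level_counts[["medium"]],
        n_large = cs$level_counts[["large"]]
      )
    })
  })
}

#' Anti-saccade difference curve
#'
#' The cumulative percentage of correct anti-saccades minus the cumulative
#' percentage of direction errors (both express and regular), as a
#' percentage of all anti-task trials, on the 6-ms histogram grid from
#' stimulus onset to the end of the simulation window. The curve dips below
#' zero while early errors outnumber correct responses and rises as the
#' voluntary command takes over.
#'
#' @param records Classified trial records (must contain anti-task trials).
#' @param bin_ms Bin width in ms (default 6).
#' @param t_max End of the curve (default 600 ms).
#' @return Tibble of class `difference_curve` with `time` (bin start),
#'   `cum_correct_pct`, `cum_error_pct` and `diff`.
#' @export
anti_difference_curve <- function(records, bin_ms = 6, t_max = 600) {
  anti <- records[records$task == "anti", ]
  if (nrow(anti) == 0) stop("no anti-task records")
  n_anti <- nrow(anti)
  correct <- anti$srt[anti$saccade_type == "correct_anti"]
  err <- anti$srt[anti$saccade_type %in% c("express_error", "regular_error")]
  starts <- seq(0, t_max - bin_ms, by = bin_ms)
  ends <- starts + bin_ms
  cum_c <- purrr::map_int(ends, function(e) sum(correct < e))
  cum_e <- purrr::map_int(ends, function(e) sum(err < e))
  out <- tibble::tibble(
    time = starts,
    cum_correct_pct = 100 * cum_c / n_anti,
    cum_error_pct = 100 * cum_e / n_anti,
    diff = 100 * (cum_c - cum_e) / n_anti
  )
  class(out) <- c("difference_curve", class(out))
  attr(out, "bin_ms") <- bin_ms
  out
}

#' Voluntary override time
#'
#' The time at which the voluntary drive starts to overcome the automated
#' drive: the first point after the global minimum of the anti-saccade
#' difference curve that rises by at least one percentage point over the
#' value just before it. Returns `NA` if the curve never recovers.
#'
#' @param curve A [anti_difference_curve()] result (or any tibble with
#'   `time` and `diff` columns).
#' @param rise Minimum rise per bin that counts as recovery (default 1
#'   percentage point).
#' @return Override time in ms, or `NA`.
#' @export
voluntary_override_time <- function(curve, rise = 1) {
  v <- curve$diff
  i_min <- which.min(v)
  j <- i_min + 1
  while (j <= length(v)) {
    if (v[j] - v[j - 1] >= rise) return(curve$time[j])
    j <- j + 1
  }
  NA_real_
}

#' Early-to-late regular-error ratio
#'
#' Count of regular-latency direction errors in the early window divided by
#' the count in the late window (both inclusive); the statistic used to
#' quantify the effect of the inhibitory crosstalk.
#'
#' @param records Classified trial records.
#' @param early Early window in ms (default `c(140, 199)`).
#' @param late Late window in ms (default `c(200, 259)`).
#' @return The ratio, or `NA` when the late count is zero.
#' @export
early_late_ratio <- function(records, early = c(140, 199),
                             late = c(200, 259)) {
  stopifnot(early[2] < late[1])
  err <- records$srt[records$saccade_type == "regular_error"]
  n_early <- sum(err >= early[1] & err <= early[2])
  n_late <- sum(err >= late[1] & err <= late[2])
  if (n_late == 0) return(NA_real_)
  n_early / n_late
}
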