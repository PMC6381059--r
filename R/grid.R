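#' The ten varied attributes and their level values
#'
#' Controlled deterministic variability: each varied attribute takes one of
#' three monotonically increasing values (small, medium, large). Rates of
#' response are fractions per ms. Inputs 4-8 share a single onset delay per
#' trial (a common internal drive for the voluntary and inhibitory inputs).
#'
#' @return Named list mapping attribute code to its three level values
#'   (named `small`, `medium`, `large`).
#' @export
attribute_levels <- function() {
  lv <- function(s, m, l) c(small = s, medium = m, large = l)
  list(
    onset_delay = lv(140, 155, 170),
    am_ror      = lv(0.04, 0.06, 0.08),
    am_max      = lv(4, 6, 8),
    vm_ror      = lv(0.05, 0.10, 0.15),
    vf_max      = lv(4, 6, 8),
    vp_max      = lv(4, 6, 8),
    gate_ror    = lv(0.05, 0.10, 0.15),
    gate_max    = lv(4, 6, 8),
    pi_ror      = lv(0.05, 0.10, 0.15),
    pi_max      = lv(4, 6, 8)
  )
}

#' Codes and display names of the varied attributes
#'
#' @return Tibble with columns `attribute` (code) and `label` (display name).
#' @export
varied_attributes <- function() {
  tibble::tibble(
    attribute = names(attribute_levels()),
    label = c("Onset delay", "Auto-motor RoR", "Auto-motor MAX",
              "Vol-motor RoR", "Vol-fixation MAX", "Vol-prep MAX",
              "Inhibit-gate RoR", "Inhibit-gate MAX",
              "Periph-inhib RoR", "Periph-inhib MAX")
  )
}

#' Resolve setting levels into concrete attribute values
#'
#' Adds (or refreshes) the numeric attribute columns implied by the
#' `<attribute>_level` columns of a settings table.
#'
#' @param settings Tibble with a `task` column and the ten
#'   `<attribute>_level` columns (values `"small"`, `"medium"`, `"large"`).
#' @return The settings tibble with one numeric column per varied attribute.
#' @examples
#' g <- saccade_grid(tasks = "pro")
#' g[1, c("onset_delay", "am_ror")]
#' @export
resolve_settings <- function(settings) {
  levels_map <- attribute_levels()
  for (attr in names(levels_map)) {
    lv_col <- settings[[paste0(attr, "_level")]]
    if (is.null(lv_col)) stop("missing level column for attribute: ", attr)
    bad <- !lv_col %in% c("small", "medium", "large")
    if (any(bad)) stop("unknown level label: ", unique(lv_col[bad])[1])
    settings[[attr]] <- unname(levels_map[[attr]][lv_col])
  }
  settings
}

#' Enumerate the full deterministic trial grid
#'
#' Every combination of the three levels of the ten varied attributes, for
#' each requested task: 3^10 = 59,049 settings per task, 118,098 in the
#' default pro + anti grid. Enumeration is lexicographic over (task, then the
#' attributes in their documented order, small < medium < large), so trial
#' ids are stable identifiers across runs.
#'
#' The stimulus side is fixed (right by default): the field is mirror
#' symmetric, so the left-side grid is redundant and is only used as a
#' symmetry check.
#'
#' @param tasks Character vector, subset of `c("pro", "anti")`.
#' @param stimulus_side `"right"` (default) or `"left"`.
#' @param resolve Add the numeric attribute columns (default `TRUE`).
#' @return Tibble with one row per trial: `trial_id`, `task`,
#'   `stimulus_side`, the ten `<attribute>_level` columns and (if resolved)
#'   the ten numeric attribute columns.
#' @examples
#' nrow(saccade_grid()) # 118098
#' @export
saccade_grid <- function(tasks = c("pro", "anti"), stimulus_side = "right",
                         resolve = TRUE) {
  tasks <- match.arg(tasks, c("pro", "anti"), several.ok = TRUE)
  stimulus_side <- match.arg(stimulus_side, c("right", "left"))
  lv <- c("small", "medium", "large")
  args <- c(
    list(task = tasks),
    stats::setNames(rep(list(lv), 10), paste0(names(attribute_levels()), "_level"))
  )
  g <- rlang::exec(tidyr::expand_grid, !!!args)
  g <- tibble::add_column(g, trial_id = seq_len(nrow(g)), .before = 1)
  g <- tibble::add_column(g, stimulus_side = stimulus_side, .after = "task")
  if (resolve) g <- resolve_settings(g)
  g
}

#' Export a settings grid as CSV
#'
#' One row per trial: trial id, task, level labels and resolved values.
#'
#' @param grid A settings grid from [saccade_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_grid_csv <- function(grid, path) {
  readr::write_csv(resolve_settings(grid), path)
  invisible(path)
}
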