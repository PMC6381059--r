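#' Run configuration
#'
#' A declarative description of a simulation run: field-parameter and
#' timeline overrides, grid options, post-hoc options and the output
#' directory. An empty configuration reproduces the baseline experiment.
#' Configurations round-trip losslessly through YAML.
#'
#' @param params A [field_params()].
#' @param timeline A [trial_timeline()].
#' @param tasks Tasks to run.
#' @param stimulus_side Stimulus side.
#' @param ablations Ablated input names.
#' @param crosstalk Crosstalk fraction (0 disables).
#' @param intentional_state Intentional-state filter mode (see
#'   [intentional_state_filter()]).
#' @param output_dir Output directory for the run products.
#' @return A `run_config` object.
#' @export
run_config <- function(params = field_params(), timeline = trial_timeline(),
                       tasks = c("pro", "anti"), stimulus_side = "right",
                       ablations = character(), crosstalk = 0,
                       intentional_state = "off", output_dir = ".") {
  structure(
    list(version = 1L, params = params, timeline = timeline, tasks = tasks,
         stimulus_side = stimulus_side, ablations = ablations,
         crosstalk = crosstalk, intentional_state = intentional_state,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Save a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  plain <- config
  plain$params <- unclass(config$params)
  plain$timeline <- unclass(config$timeline)
  plain <- unclass(plain)
  yaml::write_yaml(plain, path, precision = 17L)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Missing fields take their baseline defaults, so an empty file reproduces
#' the baseline simulation.
#'
#' @param path YAML file written by [save_run_config()] (or by hand).
#' @return A `run_config` object.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  base <- run_config()
  cfg <- run_config(
    params = do.call(field_params,
                     utils::modifyList(list(), y$params %||% list())),
    timeline = do.call(trial_timeline,
                       utils::modifyList(list(), y$timeline %||% list())),
    tasks = unlist(y$tasks %||% base$tasks),
    stimulus_side = y$stimulus_side %||% base$stimulus_side,
    ablations = as.character(unlist(y$ablations %||% character())),
    crosstalk = y$crosstalk %||% 0,
    intentional_state = y$intentional_state %||% "off",
    output_dir = y$output_dir %||% "."
  )
  cfg
}

baseline_params_flags <- function(params, timeline) {
  non_default <- function(obj, ref) {
    nm <- names(ref)
    nm[!purrr::map2_lgl(obj[nm], ref[nm], identical)]
  }
  c(non_default(params, field_params()),
    non_default(timeline, trial_timeline()))
}

#' Execute a configured run and write its products
#'
#' Runs the configured grid (with any post-hoc options), then writes the
#' trial records, the behavioural summary, the attribute-effect and
#' selection tables, the anti-saccade difference curve and a manifest
#' sufficient to reproduce the run, all as plain files in the configured
#' output directory.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @param grid Optional settings tibble overriding the configured grid
#'   (custom or reduced designs); the default runs the full factorial grid.
#' @return Invisibly, a list with the records, the summary and the paths of
#'   the written products.
#' @export
cli_run <- function(config = run_config(), quiet = FALSE, grid = NULL) {
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(grid)) {
    grid <- saccade_grid(tasks = config$tasks,
                         stimulus_side = config$stimulus_side)
  }
  say("simulating %d trials ...", nrow(grid))
  t0 <- Sys.time()
  records <- run_trials(grid, params = config$params,
                        timeline = config$timeline,
                        ablations = config$ablations,
                        crosstalk = config$crosstalk)
  dt <- as.numeric(Sys.time() - t0, units = "secs")
  say("done in %.1f s (%.0f trials/s)", dt, nrow(grid) / dt)
  analysed <- intentional_state_filter(records, config$intentional_state)
  smry <- summarize_behavior(analysed)
  paths <- list(
    records = file.path(out_dir, "records.csv"),
    summary = file.path(out_dir, "summary.csv"),
    effects = file.path(out_dir, "attribute_effects.csv"),
    selection = file.path(out_dir, "selection_effects.csv"),
    difference_curve = file.path(out_dir, "difference_curve.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  rec_out <- dplyr::select(records, "trial_id", "task", "stimulus_side",
                           dplyr::ends_with("_level"), "srt", "landing_x",
                           "direction", "saccade_type")
  readr::write_csv(rec_out, paths$records)
  readr::write_csv(smry, paths$summary)
  # effect tables need every behaviour and level populated; custom or
  # reduced grids may not satisfy that, so skip what cannot be computed
  try_write <- function(fn, path, what) {
    tryCatch(readr::write_csv(fn(), path),
             error = function(e) say("skipping %s: %s", what,
                                     conditionMessage(e)))
  }
  try_write(function() attribute_effects(analysed), paths$effects,
            "attribute effects")
  try_write(function() selection_effects(analysed), paths$selection,
            "selection effects")
  if (any(analysed$task == "anti")) {
    readr::write_csv(anti_difference_curve(analysed), paths$difference_curve)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("saccfield")),
    params = unclass(config$params), timeline = unclass(config$timeline),
    tasks = config$tasks, stimulus_side = config$stimulus_side,
    ablations = config$ablations, crosstalk = config$crosstalk,
    intentional_state = config$intentional_state,
    non_default_parameters = baseline_params_flags(config$params,
                                                   config$timeline),
    n_trials = nrow(records)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(records = records, summary = smry, paths = paths))
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `saccfield` command-line script
#' (`inst/cli/saccfield.R`): `run` executes a configured simulation,
#' `export-grid` writes the settings grid, `compare` reports a recorded run
#' against the packaged human reference, `posthoc` re-runs with an ablation,
#' intentional-state filter or crosstalk enabled.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the result of the dispatched command.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: saccfield <command> [options]",
    "commands:",
    "  run [--config FILE] [--out DIR]          baseline (or configured) grid",
    "  posthoc ablate --input NAME [--out DIR]  re-run with an input removed",
    "  posthoc intent --mode MODE [--out DIR]   intentional-state filter",
    "  posthoc crosstalk [--fraction F] [--out DIR]",
    "  compare --records FILE                   side-by-side vs human data",
    "  export-grid --out FILE                   settings grid as CSV",
    sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(NULL)) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  cfg_from <- function() {
    cfile <- opt("--config")
    cfg <- if (is.null(cfile)) run_config() else load_run_config(cfile)
    cfg$output_dir <- opt("--out", cfg$output_dir)
    cfg
  }
  switch(cmd,
    "run" = invisible(cli_run(cfg_from())),
    "posthoc" = {
      sub <- args[2]
      cfg <- cfg_from()
      if (identical(sub, "ablate")) {
        cfg$ablations <- ablate(cfg$ablations, opt("--input"))
      } else if (identical(sub, "intent")) {
        cfg$intentional_state <- opt("--mode", "combined")
      } else if (identical(sub, "crosstalk")) {
        cfg$crosstalk <- as.numeric(opt("--fraction", "0.25"))
      } else {
        stop("unknown posthoc subcommand: ", sub)
      }
      invisible(cli_run(cfg))
    },
    "compare" = {
      rec <- readr::read_csv(opt("--records"), show_col_types = FALSE)
      cmp <- compare_to_human(summarize_behavior(rec))
      print(as.data.frame(cmp))
      invisible(cmp)
    },
    "export-grid" = {
      path <- opt("--out", "grid.csv")
      export_grid_csv(saccade_grid(), path)
      invisible(path)
    },
    { cat(usage, "\n"); stop("unknown command: ", cmd) }
  )
}
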