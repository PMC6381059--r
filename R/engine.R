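engine_profiles <- function(params, stimulus_side) {
  stim_mu <- if (identical(stimulus_side, "left")) -2.5 else 2.5
  k_fix <- gaussian_profile(0, params)
  x <- node_positions(params)
  list(
    k_stim = gaussian_profile(stim_mu, params),
    k_mirror = gaussian_profile(-stim_mu, params),
    k_fix = k_fix,
    k_prep = pmax(gaussian_profile(-2.5, params), gaussian_profile(2.5, params)),
    pi_shape = 1 - k_fix / params$input_amp,
    x = x,
    eligible = which(abs(x) > params$fixation_exclusion_radius) - 1L
  )
}

sim_chunk_compiled <- function(resolved, params, timeline, w, ablations,
                               crosstalk, trace = FALSE, dedup = TRUE) {
  fx <- fixed_input_attributes()
  amp <- params$input_amp
  side <- unique(resolved$stimulus_side)
  stopifnot(length(side) == 1L)
  prof <- engine_profiles(params, side)
  par <- c(
    params[c("n_nodes", "dt", "tau", "beta", "threshold",
             "resting_potential", "input_amp")],
    prof, list(w = unclass(w))
  )
  ramp <- (timeline$stimulus_on_t - timeline$fixation_acquired_t) -
    resolved$onset_delay
  if (any(ramp <= 0)) stop("voluntary-preparation ramp duration must be positive")
  zero_if <- function(name, v) if (name %in% ablations) 0 * v else v
  trials <- list(
    onset_delay = as.double(resolved$onset_delay),
    am_ror = zero_if("automated_motor", as.double(resolved$am_ror)),
    am_max = as.double(resolved$am_max),
    vm_ror = zero_if("voluntary_motor", as.double(resolved$vm_ror)),
    vf_max = as.double(resolved$vf_max),
    vp_ror = zero_if("voluntary_preparation",
                     resolved$vp_max / (amp * ramp)),
    vp_max = as.double(resolved$vp_max),
    gate_ror = zero_if("inhibitory_gate", as.double(resolved$gate_ror)),
    gate_max = as.double(resolved$gate_max),
    pi_ror = zero_if("peripheral_inhibition", as.double(resolved$pi_ror)),
    pi_max = as.double(resolved$pi_max),
    anti = as.integer(resolved$task == "anti"),
    trial_id = as.integer(resolved$trial_id)
  )
  if (dedup) {
    key <- paste(trials$onset_delay, trials$vp_max, trials$vf_max,
                 trials$gate_max, trials$pi_max)
    cfg <- match(key, unique(key))
    trials$config_id <- cfg - 1L
    trials$config_rep <- match(seq_along(unique(key)), cfg) - 1L
  }
  opts <- list(
    vt_delay = fx$vt_delay,
    vt_ror = if ("visual_transient" %in% ablations) 0 else fx$vt_ror,
    vt_max = fx$vt_max, vt_rise = 50,
    am_delay = fx$am_delay, af_delay = fx$af_delay,
    af_ror = if ("automated_fixation" %in% ablations) 0 else fx$af_ror,
    af_max = fx$af_max,
    vf_ror = if ("voluntary_fixation" %in% ablations) 0 else fx$vf_ror,
    crosstalk = crosstalk, trace = trace, dedup = dedup
  )
  sim_batch_cpp(par, unclass(timeline), trials, opts)
}

#' Simulate one trial with the step-by-step reference engine
#'
#' Pure-R trial simulation applying the literal per-step input increments and
#' field updates one time point at a time. It is far slower than the batched
#' engine behind [run_trials()] but is the transparent reference against
#' which that engine is validated, and can return full state trajectories.
#'
#' @param resolved One resolved trial (one-row tibble or named list; see
#'   [resolve_settings()]).
#' @param params A [field_params()].
#' @param timeline A [trial_timeline()].
#' @param ablations Input names forced to rate-of-response zero.
#' @param crosstalk Voluntary-to-automated crosstalk fraction (0 disables).
#' @param trace If `TRUE`, also return the full `u`, `a` and `c_ext`
#'   trajectories (matrices time x nodes) and the time grid.
#' @return A list with `srt` (ms or `NA`), `node`, `landing_x`, `direction`,
#'   and, when `trace = TRUE`, `t`, `u`, `a`, `c_ext`.
#' @export
run_trial_reference <- function(resolved, params = field_params(),
                                timeline = trial_timeline(),
                                ablations = character(), crosstalk = 0,
                                trace = FALSE) {
  bank <- new_input_bank(resolved, timeline, params, ablations)
  w <- lateral_weights(params)
  state <- field_state(timeline$fixation_acquired_t, params)
  nsteps <- round((timeline$max_sim_t - timeline$fixation_acquired_t) / params$dt)
  if (trace) {
    tr_u <- matrix(NA_real_, nsteps, params$n_nodes)
    tr_a <- tr_u; tr_c <- tr_u
    tr_t <- numeric(nsteps)
  }
  event <- NULL
  for (s in seq_len(nsteps)) {
    # inputs are advanced to the new time point before the field update
    bank <- update_input_bank(bank, state$t + params$dt)
    c_ext <- sum_inputs(bank, crosstalk)
    state <- step_field(state, c_ext, w, params)
    if (trace) {
      tr_u[s, ] <- state$u; tr_a[s, ] <- state$a; tr_c[s, ] <- c_ext
      tr_t[s] <- state$t
    }
    event <- detect_saccade(state, params)
    if (!is.null(event)) break
  }
  out <- if (is.null(event)) {
    list(srt = NA_real_, node = NA_integer_, landing_x = NA_real_,
         direction = NA_character_)
  } else {
    list(srt = event$srt, node = event$node, landing_x = event$x,
         direction = event$direction)
  }
  if (trace) {
    keep <- seq_len(if (is.null(event)) nsteps else s)
    out$t <- tr_t[keep]
    out$u <- tr_u[keep, , drop = FALSE]
    out$a <- tr_a[keep, , drop = FALSE]
    out$c_ext <- tr_c[keep, , drop = FALSE]
  }
  out
}

#' Run a set of trials through the field model
#'
#' Simulates every row of a settings table from fixation acquisition to the
#' saccade (or the simulation limit) and classifies the outcome. The default
#' engine batches trials and shares the pre-stimulus epoch across trials with
#' identical pre-stimulus settings; results are independent of the batching
#' (`chunk_size`) and identical to the step-by-step reference engine.
#'
#' The model contains no random variables: repeated runs are identical.
#'
#' @param settings Settings tibble from [saccade_grid()] (level columns are
#'   resolved automatically if the numeric columns are absent).
#' @param params A [field_params()].
#' @param timeline A [trial_timeline()].
#' @param ablations Character vector of input names whose rate of response is
#'   forced to zero (post-hoc investigation 1).
#' @param crosstalk Fraction of the mirrored voluntary motor vector
#'   subtracted from the automated motor input at every step (post-hoc
#'   investigation 3); 0 disables.
#' @param windows [saccade_windows()] used for classification.
#' @param engine `"compiled"` (batched, default) or `"reference"` (pure R,
#'   for small sets).
#' @param chunk_size Trials per compiled batch (default 16384).
#' @return The settings tibble with columns `srt` (ms, `NA` when no saccade),
#'   `landing_x` (mm), `direction` and `saccade_type` appended.
#' @examples
#' \donttest{
#' g <- saccade_grid()[c(1, 59050), ]
#' run_trials(g)[, c("task", "srt", "direction", "saccade_type")]
#' }
#' @export
run_trials <- function(settings, params = field_params(),
                       timeline = trial_timeline(), ablations = character(),
                       crosstalk = 0, windows = saccade_windows(),
                       engine = c("compiled", "reference"),
                       chunk_size = 16384L) {
  engine <- match.arg(engine)
  if (!all(names(attribute_levels()) %in% names(settings))) {
    settings <- resolve_settings(settings)
  }
  if (!"trial_id" %in% names(settings)) {
    settings$trial_id <- seq_len(nrow(settings))
  }
  if (!"stimulus_side" %in% names(settings)) settings$stimulus_side <- "right"
  stopifnot(crosstalk >= 0, crosstalk <= 1)
  bad <- setdiff(ablations, input_names())
  if (length(bad)) stop("unknown input name(s): ", paste(bad, collapse = ", "))

  if (engine == "reference") {
    res <- purrr::map(seq_len(nrow(settings)), function(i) {
      r <- run_trial_reference(settings[i, ], params, timeline, ablations,
                               crosstalk)
      tibble::tibble(srt = r$srt, landing_x = r$landing_x,
                     direction = r$direction %||% NA_character_)
    })
    out <- dplyr::bind_cols(settings, dplyr::bind_rows(res))
  } else {
    w <- lateral_weights(params)
    x <- node_positions(params)
    chunks <- split(seq_len(nrow(settings)),
                    ceiling(seq_len(nrow(settings)) / chunk_size))
    res <- purrr::map(chunks, function(idx) {
      ch <- settings[idx, ]
      parts <- purrr::map(split(seq_len(nrow(ch)), ch$stimulus_side),
        function(j) {
          r <- sim_chunk_compiled(ch[j, ], params, timeline, w, ablations,
                                  crosstalk)
          tibble::tibble(.row = j, srt = r$srt,
                         landing_x = x[r$node],
                         direction = dplyr::if_else(x[r$node] > 0,
                                                    "right", "left"))
        })
      dplyr::arrange(dplyr::bind_rows(parts), .data$.row)[-1]
    })
    out <- dplyr::bind_cols(settings, dplyr::bind_rows(res))
  }
  out$saccade_type <- classify_saccade(out$task, out$stimulus_side,
                                       out$direction, out$srt, windows)
  attr(out, "windows") <- windows
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full deterministic experiment
#'
#' Convenience wrapper: enumerates the grid, simulates every trial, and
#' bundles the classified records with the behavioural summary and the run
#' configuration into a `saccade_sim` object with [tidy()], [glance()],
#' `summary()` and [autoplot()] methods.
#'
#' @inheritParams run_trials
#' @param tasks Tasks to simulate (default both).
#' @param stimulus_side Stimulus side for the canonical grid.
#' @param ... Passed on to [run_trials()] (e.g. `ablations`, `crosstalk`).
#' @return A `saccade_sim` object.
#' @export
simulate_experiment <- function(tasks = c("pro", "anti"),
                                stimulus_side = "right",
                                params = field_params(),
                                timeline = trial_timeline(), ...) {
  grid <- saccade_grid(tasks = tasks, stimulus_side = stimulus_side)
  records <- run_trials(grid, params = params, timeline = timeline, ...)
  structure(
    list(records = records, params = params, timeline = timeline,
         options = list(...), summary = summarize_behavior(records)),
    class = "saccade_sim"
  )
}

#' @export
print.saccade_sim <- function(x, ...) {
  cat(sprintf("<saccade_sim> %d trials\n", nrow(x$records)))
  print(x$summary)
  invisible(x)
}

#' @export
summary.saccade_sim <- function(object, ...) object$summary
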