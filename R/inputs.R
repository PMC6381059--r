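#' Fixed attributes of the stimulus-locked inputs
#'
#' The visual transient and the automated fixation input are identical on
#' every trial (all trials share the same external stimulation), and the
#' automated motor input has a fixed afferent onset delay. The voluntary
#' fixation input has a fixed rate of response. These constants are collected
#' here so they can be overridden only deliberately.
#'
#' Rates of response are expressed as fractions per ms (0.15 means 15% of the
#' spatial profile added per millisecond).
#'
#' @return Named list of the fixed attributes.
#' @export
fixed_input_attributes <- function() {
  list(
    vt_delay = 50, vt_ror = 0.15, vt_max = 8,
    am_delay = 60,
    af_delay = 60, af_ror = 0.10, af_max = 6,
    vf_ror = 0.10
  )
}

input_names <- function() {
  c("visual_transient", "automated_motor", "automated_fixation",
    "voluntary_motor", "voluntary_fixation", "voluntary_preparation",
    "inhibitory_gate", "peripheral_inhibition")
}

#' Per-input attribute schedule for one trial
#'
#' Resolves one trial's settings into the concrete attributes of each of the
#' eight inputs: onset reference and delay, rate of response, cap, and the
#' centre(s) of activity. The goal position of the voluntary motor and
#' inhibitory gate inputs is the stimulus position on pro-saccade trials and
#' its mirror on anti-saccade trials. The voluntary-preparation rate is
#' derived from its cap so that both of its peaks reach the cap exactly at
#' the expected stimulus onset.
#'
#' Ablating an input (post-hoc investigation 1) sets its rate of response to
#' zero: inputs that rise from zero then never appear, and inputs that start
#' at strength are frozen there.
#'
#' @param resolved One resolved trial (a one-row data frame or named list with
#'   the numeric attribute columns produced by [resolve_settings()]).
#' @param timeline A [trial_timeline()].
#' @param params A [field_params()].
#' @param ablations Character vector of input names whose rate of response is
#'   forced to zero.
#' @return Named list (one element per input) of attribute lists.
#' @export
input_schedule <- function(resolved, timeline = trial_timeline(),
                           params = field_params(), ablations = character()) {
  fx <- fixed_input_attributes()
  bad <- setdiff(ablations, input_names())
  if (length(bad)) stop("unknown input name(s): ", paste(bad, collapse = ", "))
  stim_mu <- if (identical(resolved$stimulus_side, "left")) -2.5 else 2.5
  goal_mu <- if (identical(resolved$task, "anti")) -stim_mu else stim_mu
  ramp <- (timeline$stimulus_on_t - timeline$fixation_acquired_t) -
    resolved$onset_delay
  if (ramp <= 0) stop("voluntary-preparation ramp duration must be positive")
  vp_ror <- resolved$vp_max / (params$input_amp * ramp)
  zero_if <- function(name, ror) if (name %in% ablations) 0 else ror
  list(
    visual_transient = list(
      onset = timeline$stimulus_on_t + fx$vt_delay,
      ror = zero_if("visual_transient", fx$vt_ror),
      max_val = fx$vt_max, mu = stim_mu, rise_ms = 50),
    automated_motor = list(
      onset = timeline$stimulus_on_t + fx$am_delay,
      ror = zero_if("automated_motor", resolved$am_ror),
      max_val = resolved$am_max, mu = stim_mu),
    automated_fixation = list(
      onset = timeline$fixation_off_t + fx$af_delay,
      ror = zero_if("automated_fixation", fx$af_ror),
      max_val = fx$af_max, mu = 0),
    voluntary_motor = list(
      onset = timeline$stimulus_on_t + resolved$onset_delay,
      ror = zero_if("voluntary_motor", resolved$vm_ror),
      max_val = Inf, mu = goal_mu),
    voluntary_fixation = list(
      onset = timeline$stimulus_on_t + resolved$onset_delay,
      ror = zero_if("voluntary_fixation", fx$vf_ror),
      max_val = resolved$vf_max, mu = 0),
    voluntary_preparation = list(
      onset = timeline$fixation_acquired_t + resolved$onset_delay,
      ror = zero_if("voluntary_preparation", vp_ror),
      max_val = resolved$vp_max, mu = c(-2.5, 2.5)),
    inhibitory_gate = list(
      onset = timeline$stimulus_on_t + resolved$onset_delay,
      ror = zero_if("inhibitory_gate", resolved$gate_ror),
      max_val = resolved$gate_max, mu = goal_mu),
    peripheral_inhibition = list(
      onset = timeline$stimulus_on_t + resolved$onset_delay,
      ror = zero_if("peripheral_inhibition", resolved$pi_ror),
      max_val = resolved$pi_max, mu = 0)
  )
}

#' Initialise the input bank for one trial
#'
#' Builds the eight input vectors in their trial-start states: the fixation
#' inputs (automated and voluntary) at their caps over the fovea, the
#' inhibitory gate a uniform wall at its full depth, the peripheral
#' inhibition at full depth everywhere except a smooth notch sparing the
#' fovea, and the stimulus-driven and voluntary motor/preparation inputs at
#' zero.
#'
#' @inheritParams input_schedule
#' @return An object of class `input_bank`: the eight vectors, the schedule,
#'   the spatial profiles, and the trial clock.
#' @export
new_input_bank <- function(resolved, timeline = trial_timeline(),
                           params = field_params(), ablations = character()) {
  sched <- input_schedule(resolved, timeline, params, ablations)
  amp <- params$input_amp
  k_stim <- gaussian_profile(sched$automated_motor$mu, params)
  k_goal <- gaussian_profile(sched$voluntary_motor$mu, params)
  k_fix <- gaussian_profile(0, params)
  k_prep <- pmax(gaussian_profile(-2.5, params), gaussian_profile(2.5, params))
  pi_shape <- 1 - k_fix / amp
  n <- params$n_nodes
  v <- list(
    visual_transient = numeric(n),
    automated_motor = numeric(n),
    automated_fixation = k_fix * sched$automated_fixation$max_val / amp,
    voluntary_motor = numeric(n),
    voluntary_fixation = k_fix * sched$voluntary_fixation$max_val / amp,
    voluntary_preparation = numeric(n),
    inhibitory_gate = rep(-sched$inhibitory_gate$max_val, n),
    peripheral_inhibition = -sched$peripheral_inhibition$max_val * pi_shape
  )
  structure(
    list(v = v, schedule = sched, params = params, timeline = timeline,
         profiles = list(k_stim = k_stim, k_goal = k_goal, k_fix = k_fix,
                         k_prep = k_prep, pi_shape = pi_shape)),
    class = "input_bank"
  )
}

# --- per-input update rules (literal per-step increments) -------------------
# Each rule is applied at the advanced time t: an increment of
# k * RoR * dt is added (or removed) whenever t is past the input's onset.

#' Update the visual transient input
#'
#' A brief sensory burst at the stimulus site: it rises at its rate of
#' response from 50 ms after stimulus onset, then fades at half that rate
#' starting 50 ms after its response onset until it is zero everywhere.
#'
#' @param bank An `input_bank`.
#' @param t Current time (ms, relative to stimulus onset).
#' @return The updated bank.
#' @export
update_visual_transient <- function(bank, t) {
  s <- bank$schedule$visual_transient
  p <- bank$params
  k <- bank$profiles$k_stim
  fade_start <- s$onset + s$rise_ms
  if (t > s$onset && t <= fade_start) {
    cap <- s$max_val * k / p$input_amp
    bank$v$visual_transient <-
      pmin(cap, bank$v$visual_transient + k * s$ror * p$dt)
  } else if (t > fade_start) {
    bank$v$visual_transient <-
      pmax(0, bank$v$visual_transient - k * (s$ror / 2) * p$dt)
  }
  bank
}

#' Update the automated motor input
#'
#' The externally triggered, self-propagating motor command towards the
#' stimulus: rises from 60 ms after stimulus onset at its trial-specific rate
#' and holds at its trial-specific cap until the saccade.
#'
#' @inheritParams update_visual_transient
#' @return The updated bank.
#' @export
update_automated_motor <- function(bank, t) {
  s <- bank$schedule$automated_motor
  p <- bank$params
  if (t > s$onset) {
    k <- bank$profiles$k_stim
    cap <- s$max_val * k / p$input_amp
    bank$v$automated_motor <-
      pmin(cap, bank$v$automated_motor + k * s$ror * p$dt)
  }
  bank
}

#' Update the automated fixation input
#'
#' Foveal, stimulus-dependent fixation activity: at its cap while the
#' fixation point is lit, fading at its rate of response from 60 ms after
#' fixation offset (i.e. during the gap) until it reaches zero.
#'
#' @inheritParams update_visual_transient
#' @return The updated bank.
#' @export
update_automated_fixation <- function(bank, t) {
  s <- bank$schedule$automated_fixation
  p <- bank$params
  if (t > s$onset) {
    k <- bank$profiles$k_fix
    bank$v$automated_fixation <-
      pmax(0, bank$v$automated_fixation - k * s$ror * p$dt)
  }
  bank
}

#' Update the voluntary motor input
#'
#' The internally initiated motor command at the task goal (the stimulus on
#' pro trials, its mirror on anti trials): rises without bound from stimulus
#' onset plus the trial's shared voluntary onset delay until the saccade.
#'
#' @inheritParams update_visual_transient
#' @return The updated bank.
#' @export
update_voluntary_motor <- function(bank, t) {
  s <- bank$schedule$voluntary_motor
  p <- bank$params
  if (t > s$onset) {
    k <- bank$profiles$k_goal
    bank$v$voluntary_motor <- bank$v$voluntary_motor + k * s$ror * p$dt
  }
  bank
}

#' Update the voluntary fixation input
#'
#' Internally sustained foveal fixation activity: at its trial-specific cap
#' from trial start, decaying towards zero in unison with the onset of the
#' voluntary motor input.
#'
#' @inheritParams update_visual_transient
#' @return The updated bank.
#' @export
update_voluntary_fixation <- function(bank, t) {
  s <- bank$schedule$voluntary_fixation
  p <- bank$params
  if (t > s$onset) {
    k <- bank$profiles$k_fix
    bank$v$voluntary_fixation <-
      pmax(0, bank$v$voluntary_fixation - k * s$ror * p$dt)
  }
  bank
}

#' Update the voluntary preparation input
#'
#' The two-peaked anticipatory build-up over both possible stimulus sites:
#' rises from fixation acquisition plus the shared onset delay at a rate
#' chosen so both peaks reach the cap exactly at the expected stimulus onset,
#' then holds until the saccade.
#'
#' @inheritParams update_visual_transient
#' @return The updated bank.
#' @export
update_voluntary_preparation <- function(bank, t) {
  s <- bank$schedule$voluntary_preparation
  p <- bank$params
  if (t > s$onset) {
    k <- bank$profiles$k_prep
    cap <- s$max_val * k / p$input_amp
    bank$v$voluntary_preparation <-
      pmin(cap, bank$v$voluntary_preparation + k * s$ror * p$dt)
  }
  bank
}

#' Update the inhibitory gate input
#'
#' A wall of inhibition at its full trial-specific depth across the entire
#' field from trial start; from stimulus onset plus the shared delay a local
#' Gaussian opening centred on the saccade goal is carved out at the trial's
#' rate, clamped so no node becomes excitatory.
#'
#' @inheritParams update_visual_transient
#' @return The updated bank.
#' @export
update_inhibitory_gate <- function(bank, t) {
  s <- bank$schedule$inhibitory_gate
  p <- bank$params
  if (t > s$onset) {
    k <- bank$profiles$k_goal
    bank$v$inhibitory_gate <-
      pmin(0, bank$v$inhibitory_gate + k * s$ror * p$dt)
  }
  bank
}

#' Update the peripheral inhibition input
#'
#' Global inhibition of the periphery sparing the fovea (a smooth
#' complement-of-Gaussian notch at the centre); from stimulus onset plus the
#' shared delay the whole field is released uniformly at the trial's rate,
#' clamped at zero per node.
#'
#' @inheritParams update_visual_transient
#' @return The updated bank.
#' @export
update_peripheral_inhibition <- function(bank, t) {
  s <- bank$schedule$peripheral_inhibition
  p <- bank$params
  if (t > s$onset) {
    bank$v$peripheral_inhibition <-
      pmin(0, bank$v$peripheral_inhibition + p$input_amp * s$ror * p$dt)
  }
  bank
}

#' Advance all eight inputs to time `t`
#'
#' @inheritParams update_visual_transient
#' @return The updated bank.
#' @export
update_input_bank <- function(bank, t) {
  bank <- update_visual_transient(bank, t)
  bank <- update_automated_motor(bank, t)
  bank <- update_automated_fixation(bank, t)
  bank <- update_voluntary_motor(bank, t)
  bank <- update_voluntary_fixation(bank, t)
  bank <- update_voluntary_preparation(bank, t)
  bank <- update_inhibitory_gate(bank, t)
  bank <- update_peripheral_inhibition(bank, t)
  bank
}

#' Voluntary-to-automated inhibitory crosstalk
#'
#' The response-inhibition instruction of post-hoc investigation 3: the
#' voluntary motor vector is flipped about the fixation node (its toroidal
#' mirror) and a fraction of it is subtracted from the automated motor
#' vector; negative values are clamped to zero because the automated motor
#' input is not inhibitory. The voluntary motor input itself is unchanged.
#'
#' @param voluntary_motor Voluntary motor input vector.
#' @param automated_motor Automated motor input vector.
#' @param fraction Fraction of the flipped voluntary vector subtracted
#'   (default 0.25).
#' @param params A [field_params()].
#' @return The adjusted automated motor vector.
#' @export
apply_crosstalk <- function(voluntary_motor, automated_motor,
                            fraction = 0.25, params = field_params()) {
  stopifnot(fraction >= 0, fraction <= 1)
  flipped <- voluntary_motor[mirror_nodes(params)]
  pmax(0, automated_motor - fraction * flipped)
}

#' Sum the input bank into the external contribution
#'
#' Element-wise sum of the eight input vectors; when crosstalk is enabled the
#' automated motor vector is replaced by its crosstalk-adjusted version
#' before summation.
#'
#' @param bank An `input_bank`.
#' @param crosstalk_fraction 0 (disabled, the default) or the crosstalk
#'   fraction.
#' @return The external contribution vector `c_ext`.
#' @export
sum_inputs <- function(bank, crosstalk_fraction = 0) {
  v <- bank$v
  am <- if (crosstalk_fraction > 0) {
    apply_crosstalk(v$voluntary_motor, v$automated_motor,
                    crosstalk_fraction, bank$params)
  } else {
    v$automated_motor
  }
  v$visual_transient + am + v$automated_fixation + v$voluntary_motor +
    v$voluntary_fixation + v$voluntary_preparation + v$inhibitory_gate +
    v$peripheral_inhibition
}
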