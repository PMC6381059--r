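#' Neural-field model constants
#'
#' Collects every scalar constant of the collicular field model: the
#' discretisation of the motor map, the Euler integration step, the sigmoid
#' nonlinearity, the saccade-trigger threshold, and the parameters of the
#' lateral-interaction kernel and of the Gaussian input profiles.
#'
#' The field represents 10 mm of intermediate superior colliculus (both sides
#' of fixation) as `n_nodes` nodes on a ring, so node spacing is
#' `dx = 10 / n_nodes` mm. The defaults are the baseline simulation constants;
#' override individual values only to explore non-standard models.
#'
#' @param n_nodes Number of field nodes (default 100).
#' @param dx Node spacing in mm of collicular tissue (default `10 / n_nodes`).
#' @param dt Integration time step in ms (default 1).
#' @param tau Field time constant in ms (default 4).
#' @param beta Steepness of the sigmoidal output nonlinearity (default 0.09).
#' @param threshold Output activity that triggers a saccade at a non-central
#'   node (default 0.7).
#' @param resting_potential Initial internal state of every node (default -30),
#'   representing a hyperpolarised membrane potential rather than a firing rate.
#' @param lateral_sigma Width (mm) of the Gaussian used to build the lateral
#'   weight matrix (default 0.85).
#' @param lateral_scale Amplitude of that Gaussian before shifting (default 74.7).
#' @param shift_fraction Fraction of the kernel maximum subtracted to create
#'   distal inhibition (default 0.8).
#' @param input_gamma Width (mm) of the Gaussian spatial profile shared by all
#'   component inputs (default 0.6).
#' @param input_amp Peak of that profile (default 1.05).
#' @param fixation_exclusion_radius Half-width (mm) of the central zone whose
#'   threshold crossings do not trigger saccades; "non-central" locations are
#'   those strictly beyond this radius (default 1).
#'
#' @return An object of class `field_params` (a named list).
#' @examples
#' p <- field_params()
#' p$n_nodes * p$dx # torus circumference, 10 mm
#' @export
field_params <- function(n_nodes = 100L,
                         dx = 10 / n_nodes,
                         dt = 1,
                         tau = 4,
                         beta = 0.09,
                         threshold = 0.7,
                         resting_potential = -30,
                         lateral_sigma = 0.85,
                         lateral_scale = 74.7,
                         shift_fraction = 0.8,
                         input_gamma = 0.6,
                         input_amp = 1.05,
                         fixation_exclusion_radius = 1) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(
    n_nodes >= 3L, dx > 0, dt > 0, tau > 0, beta > 0,
    threshold > 0, threshold < 1,
    lateral_sigma > 0, input_gamma > 0, input_amp > 0,
    shift_fraction >= 0, fixation_exclusion_radius >= 0
  )
  structure(
    list(
      n_nodes = n_nodes, dx = dx, dt = dt, tau = tau, beta = beta,
      threshold = threshold, resting_potential = resting_potential,
      lateral_sigma = lateral_sigma, lateral_scale = lateral_scale,
      shift_fraction = shift_fraction, input_gamma = input_gamma,
      input_amp = input_amp,
      fixation_exclusion_radius = fixation_exclusion_radius
    ),
    class = "field_params"
  )
}

#' @export
print.field_params <- function(x, ...) {
  cat("<field_params>\n")
  cat(sprintf("  %d nodes x %.3g mm (torus %.3g mm), dt = %g ms, tau = %g ms\n",
              x$n_nodes, x$dx, x$n_nodes * x$dx, x$dt, x$tau))
  cat(sprintf("  sigmoid beta = %g, threshold = %g, resting u = %g\n",
              x$beta, x$threshold, x$resting_potential))
  cat(sprintf("  lateral kernel: sigma = %g mm, scale = %g, shift = %g * max\n",
              x$lateral_sigma, x$lateral_scale, x$shift_fraction))
  cat(sprintf("  input profile: gamma = %g mm, amp = %g; fixation exclusion %g mm\n",
              x$input_gamma, x$input_amp, x$fixation_exclusion_radius))
  invisible(x)
}

#' Trial timeline
#'
#' Event times of the gap paradigm, in ms relative to peripheral stimulus
#' onset. Fixation is acquired well before the gap; the fixation point
#' disappears 200 ms before the stimulus (the gap); the trial is abandoned as
#' `no_response` if no saccade has been triggered by `max_sim_t`.
#'
#' The pre-gap fixation duration is not behaviourally constrained; 800 ms of
#' stable fixation before the gap (fixation acquired at -1000 ms) is the
#' default and only affects the ramp slope of the voluntary-preparation input.
#'
#' @param fixation_acquired_t Time fixation was acquired (default -1000 ms).
#' @param fixation_off_t Fixation point offset, start of the gap (default -200 ms).
#' @param stimulus_on_t Peripheral stimulus onset (always 0 ms).
#' @param max_sim_t End of simulation (default 600 ms).
#' @return An object of class `trial_timeline` (a named list).
#' @examples
#' trial_timeline()$stimulus_on_t - trial_timeline()$fixation_off_t # 200 ms gap
#' @export
trial_timeline <- function(fixation_acquired_t = -1000,
                           fixation_off_t = -200,
                           stimulus_on_t = 0,
                           max_sim_t = 600) {
  stopifnot(fixation_acquired_t < fixation_off_t,
            fixation_off_t < stimulus_on_t,
            stimulus_on_t < max_sim_t)
  structure(
    list(fixation_acquired_t = fixation_acquired_t,
         fixation_off_t = fixation_off_t,
         stimulus_on_t = stimulus_on_t,
         max_sim_t = max_sim_t),
    class = "trial_timeline"
  )
}

#' Node positions on the motor map
#'
#' Node `i` (1-based) sits at `x = i * dx - 5` mm, so with the default 100
#' nodes the fixation point is node 50 (x = 0), the right stimulus site is
#' node 75 (x = +2.5 mm) and the left site is node 25 (x = -2.5 mm).
#'
#' @param params A [field_params()] object.
#' @return Numeric vector of length `n_nodes` with positions in mm.
#' @export
node_positions <- function(params = field_params()) {
  # (i - n/2) * dx rather than i * dx - 5: exactly antisymmetric about the
  # fixation node, so mirrored trials mirror bitwise
  (seq_len(params$n_nodes) - params$n_nodes / 2) * params$dx
}

#' Mirror permutation of the node indices
#'
#' Index of the node at the reflected position `-x` on the torus, used to
#' rotate goal-directed inputs by 180 degrees and to flip the voluntary motor
#' vector for the inhibitory-crosstalk manipulation.
#'
#' @param params A [field_params()] object.
#' @return Integer vector `m` with `m[i]` the mirror node of `i`.
#' @export
mirror_nodes <- function(params = field_params()) {
  n <- params$n_nodes
  i <- seq_len(n)
  m <- n - i             # 1-based: node i -> node n - i; node n maps to itself
  m[m == 0L] <- n
  m
}
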