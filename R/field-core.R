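#' Gaussian spatial profile on the toroidal motor map
#'
#' Every component input activates the field through the same fixed Gaussian
#' profile `k`, centred on the input's locus `mu`. Distances are measured on
#' the ring (minimum of the direct and wrap-around distance), which avoids
#' boundary artefacts at the edges of the map.
#'
#' When `mu` falls exactly on a node, distances are computed in whole node
#' units so that profiles centred at mirror-image positions are exact
#' reflections of each other.
#'
#' @param mu Centre of activity in mm; values outside `[-5, 5)` are wrapped
#'   onto the torus.
#' @param params A [field_params()] object.
#' @return Numeric vector of length `n_nodes`; the peak equals `input_amp` at
#'   the node sitting at `mu`.
#' @examples
#' k <- gaussian_profile(2.5)
#' max(k) # 1.05 at the stimulus node
#' @export
gaussian_profile <- function(mu, params = field_params()) {
  n <- params$n_nodes
  L <- n * params$dx
  # wrap mu onto [-L/2, L/2)
  mu <- ((mu + L / 2) %% L) - L / 2
  # work in node units: node i sits at i, mu at (mu + L/2)/dx; centres that
  # fall on a node snap to it exactly so mirrored profiles mirror exactly
  mu_node <- (mu + L / 2) / params$dx
  if (abs(mu_node - round(mu_node)) < 1e-9) mu_node <- round(mu_node)
  d <- abs(seq_len(n) - mu_node)
  d <- pmin(d, n - d) * params$dx
  params$input_amp * exp(-d^2 / (2 * params$input_gamma^2))
}

#' Lateral interaction weight matrix
#'
#' The field's internal connectivity: a circulant Gaussian kernel (local
#' excitation) shifted down by a fraction of its maximum (distal inhibition)
#' and scaled by the node spacing. `W[i, j]` depends only on the toroidal
#' distance between nodes `i` and `j`, so the matrix is symmetric and every
#' row is a rotation of the first.
#'
#' @param params A [field_params()] object.
#' @return An `n_nodes` x `n_nodes` matrix of class `lateral_weights`.
#' @examples
#' w <- lateral_weights()
#' w[1, 1] # local self-excitation, (74.7 - 0.8 * 74.7) * 0.1
#' @export
lateral_weights <- function(params = field_params()) {
  n <- params$n_nodes
  i <- seq_len(n)
  d <- abs(outer(i, i, "-"))
  d <- pmin(d, n - d) * params$dx
  G <- params$lateral_scale * exp(-d^2 / (2 * params$lateral_sigma^2))
  W <- (G - params$shift_fraction * max(G)) * params$dx
  class(W) <- c("lateral_weights", class(W))
  W
}

#' Sigmoidal output activity
#'
#' Converts the internal state `u` of the field into output activity in
#' `(0, 1)` through a logistic nonlinearity; `beta` controls how sharply
#' nodes saturate.
#'
#' @param u Numeric vector (or matrix) of internal states.
#' @param params A [field_params()] object.
#' @return Activity of the same shape as `u`, strictly increasing in `u`.
#' @examples
#' output_activity(0) # 0.5 at the sigmoid midpoint
#' @export
output_activity <- function(u, params = field_params()) {
  1 / (1 + exp(-params$beta * u))
}

#' Initial field state
#'
#' All nodes start at the resting potential; activity is derived from it.
#'
#' @param t Starting time in ms (relative to stimulus onset).
#' @param params A [field_params()] object.
#' @return A list with elements `t`, `u` and `a` (class `field_state`).
#' @export
field_state <- function(t, params = field_params()) {
  u <- rep(params$resting_potential, params$n_nodes)
  structure(list(t = t, u = u, a = output_activity(u, params)),
            class = "field_state")
}

#' Advance the field by one Euler step
#'
#' Implements the discretised field dynamics: the internal contribution is the
#' lateral weight matrix applied to the *current* activity, the new internal
#' state is the leaky Euler update driven by the sum of external and internal
#' contributions, and the activity is recomputed from the new state.
#'
#' @param state A `field_state` (see [field_state()]).
#' @param c_ext External contribution vector (sum of the component inputs).
#' @param w Lateral weight matrix from [lateral_weights()].
#' @param params A [field_params()] object.
#' @return The updated `field_state`, with `t` advanced by `dt`.
#' @export
step_field <- function(state, c_ext, w, params = field_params()) {
  c_int <- as.numeric(w %*% state$a)
  r <- params$dt / params$tau
  u <- (1 - r) * state$u + r * (c_ext + c_int)
  if (!all(is.finite(u))) {
    stop("non-finite internal state: field configuration is unstable")
  }
  structure(list(t = state$t + params$dt, u = u,
                 a = output_activity(u, params)),
            class = "field_state")
}

#' Threshold-based saccade detection
#'
#' A saccade is triggered when the output activity at any non-central node --
#' beyond the fixation exclusion radius -- reaches the threshold. Among the
#' crossing nodes the one with maximal activity wins; exact ties are broken
#' towards the smallest eccentricity and then leftwards. Crossings at central
#' nodes (the fixation zone) never trigger saccades.
#'
#' @param state A `field_state`.
#' @param params A [field_params()] object.
#' @return `NULL` if no saccade, otherwise a list with `node`, `x` (mm),
#'   `direction` (`"left"`/`"right"`) and `srt` (ms from stimulus onset).
#' @export
detect_saccade <- function(state, params = field_params()) {
  x <- node_positions(params)
  eligible <- abs(x) > params$fixation_exclusion_radius
  a <- state$a
  over <- eligible & a >= params$threshold
  if (!any(over)) return(NULL)
  idx <- which(over)
  # winner: maximal activity, ties -> smallest |x|, then leftmost
  idx <- idx[order(-a[idx], abs(x[idx]), x[idx])]
  node <- idx[1]
  list(node = node, x = x[node],
       direction = if (x[node] > 0) "right" else "left",
       srt = state$t)
}
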