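test_that("gaussian profile peaks at amp and respects the torus", {
  p <- field_params()
  k <- gaussian_profile(0, p)
  x <- node_positions(p)
  expect_equal(k[x == 0], p$input_amp)
  # direct scalar evaluation as independent oracle, including the wrap:
  # with mu near the seam the shortest distance crosses it (e.g. the node at
  # -4.9 is 0.15 mm from mu = 4.95, not 9.85 mm)
  k2 <- gaussian_profile(4.95, p)
  oracle <- 1.05 * exp(-pmin(abs(x - 4.95), 10 - abs(x - 4.95))^2 /
                         (2 * 0.6^2))
  expect_equal(k2, oracle, tolerance = 1e-12)
  expect_equal(k2[x == -4.9], 1.05 * exp(-0.15^2 / (2 * 0.6^2)),
               tolerance = 1e-12)
  # the scalar formula itself at toroidal distance 0.1 mm
  expect_equal(1.05 * exp(-0.1^2 / (2 * 0.6^2)), 1.0355, tolerance = 1e-4)
  # toroidal symmetry: equal values at mu + d and mu - d
  k3 <- gaussian_profile(2.5, p)
  i_mu <- which(x == 2.5)
  wrap <- function(i) ((i - 1L) %% p$n_nodes) + 1L
  for (d in c(1L, 7L, 30L)) {
    expect_identical(k3[wrap(i_mu + d)], k3[wrap(i_mu - d)])
  }
  # mirrored centres give exactly mirrored profiles
  expect_identical(gaussian_profile(-2.5, p), k3[mirror_nodes(p)])
  # out-of-range mu wraps
  expect_identical(gaussian_profile(12.5, p), k3)
})

test_that("lateral weight matrix is circulant, symmetric and centre-surround", {
  p <- field_params()
  w <- lateral_weights(p)
  # closed-form diagonal and far-field values from the kernel constants
  expect_equal(w[1, 1], (74.7 - 0.8 * 74.7) * 0.1, tolerance = 1e-12)
  far <- (74.7 * exp(-5^2 / (2 * 0.85^2)) - 0.8 * 74.7) * 0.1
  expect_equal(w[1, 51], far, tolerance = 1e-12)
  expect_equal(w[1, 51], -5.976, tolerance = 1e-3)
  expect_true(isSymmetric(unclass(w)))
  # every row is a rotation of row 1
  for (i in c(2L, 37L, 100L)) {
    rot <- c(w[1, (p$n_nodes - i + 2):p$n_nodes], w[1, 1:(p$n_nodes - i + 1)])
    expect_identical(unname(w[i, ]), unname(rot))
  }
  expect_true(all(diag(w) > 0))
  expect_true(w[1, 51] < 0) # distal inhibition
})

test_that("output activity is the logistic of the internal state", {
  p <- field_params()
  expect_equal(output_activity(0, p), 0.5)
  expect_equal(output_activity(p$resting_potential, p),
               1 / (1 + exp(2.7)), tolerance = 1e-12)
  expect_equal(output_activity(-30, p), 0.0630, tolerance = 1e-3)
  u <- sort(rnorm(50, sd = 40))
  expect_true(all(diff(output_activity(u, p)) >= 0))
  expect_true(all(output_activity(u, p) > 0 & output_activity(u, p) < 1))
})

test_that("euler update converges to the fixed point of a constant drive", {
  p <- field_params()
  w0 <- lateral_weights(p)
  w0[, ] <- 0 # isolate the leaky integrator: c_int = 0
  cc <- rep(5, p$n_nodes)
  st <- field_state(0, p)
  for (i in 1:200) st <- step_field(st, cc, w0, p)
  expect_equal(st$u, cc, tolerance = 1e-8)
  # dt = tau: the Euler coefficient vanishes and u jumps to c in one step
  p2 <- field_params(dt = 4, tau = 4)
  st2 <- field_state(0, p2)
  st2 <- step_field(st2, cc, w0, p2)
  expect_equal(st2$u, cc)
})

test_that("the resting field stays quiescent without external input", {
  p <- field_params()
  w <- lateral_weights(p)
  st <- field_state(0, p)
  zero <- rep(0, p$n_nodes)
  for (i in 1:600) {
    st <- step_field(st, zero, w, p)
    expect_null(detect_saccade(st, p))
  }
  expect_true(max(st$a) < 0.3)
})

test_that("saccade detection triggers only beyond the fixation zone", {
  p <- field_params()
  x <- node_positions(p)
  st <- field_state(10, p)
  expect_null(detect_saccade(st, p))
  # single suprathreshold node at x = +2.5
  u <- rep(p$resting_potential, p$n_nodes)
  u[x == 2.5] <- 40
  st <- structure(list(t = 150, u = u, a = output_activity(u, p)),
                  class = "field_state")
  ev <- detect_saccade(st, p)
  expect_equal(ev$x, 2.5)
  expect_equal(ev$direction, "right")
  expect_equal(ev$srt, 150)
  # a crossing confined to the fixation zone is not a saccade
  u <- rep(p$resting_potential, p$n_nodes)
  u[abs(x) <= p$fixation_exclusion_radius] <- 40
  st <- structure(list(t = 150, u = u, a = output_activity(u, p)),
                  class = "field_state")
  expect_null(detect_saccade(st, p))
  # symmetric tie resolves to the smaller eccentricity, then leftward
  u <- rep(p$resting_potential, p$n_nodes)
  u[x == 2.5] <- 40; u[x == -2.5] <- 40
  st <- structure(list(t = 150, u = u, a = output_activity(u, p)),
                  class = "field_state")
  expect_equal(detect_saccade(st, p)$x, -2.5)
})

test_that("step_field aborts on non-finite state", {
  p <- field_params()
  w <- lateral_weights(p)
  st <- field_state(0, p)
  expect_error(step_field(st, rep(Inf, p$n_nodes), w, p), "non-finite")
})
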