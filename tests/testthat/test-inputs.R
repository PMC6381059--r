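worked_anti_trial <- function(task = "anti") {
  # the worked example trial: medium automated motor, large onset delay,
  # strong gate and peripheral inhibition
  tibble::tibble(
    trial_id = 1L, task = task, stimulus_side = "right",
    onset_delay = 170, am_ror = 0.06, am_max = 6, vm_ror = 0.15,
    vf_max = 6, vp_max = 4, gate_ror = 0.10, gate_max = 8,
    pi_ror = 0.10, pi_max = 8
  )
}

advance_bank <- function(bank, from, to, params = field_params()) {
  for (t in seq(from + params$dt, to, by = params$dt)) {
    bank <- update_input_bank(bank, t)
  }
  bank
}

test_that("the schedule resolves task geometry and dependent rates", {
  tl <- trial_timeline()
  p <- field_params()
  s <- input_schedule(worked_anti_trial("anti"), tl, p)
  expect_equal(s$voluntary_motor$mu, -2.5) # anti goal mirrors the stimulus
  expect_equal(s$voluntary_motor$onset, 170)
  expect_equal(s$voluntary_motor$ror, 0.15)
  expect_equal(s$inhibitory_gate$mu, -2.5)
  expect_equal(s$visual_transient$onset, 50)
  expect_equal(s$automated_motor$mu, 2.5) # stimulus-locked in both tasks
  # voluntary preparation reaches its cap exactly at stimulus onset
  ramp <- (tl$stimulus_on_t - tl$fixation_acquired_t) - 170
  expect_equal(s$voluntary_preparation$ror * p$input_amp * ramp, 4)
  s_pro <- input_schedule(worked_anti_trial("pro"), tl, p)
  expect_equal(s_pro$voluntary_motor$mu, 2.5)
  # inputs 4, 5, 7, 8 share the stimulus-locked onset; input 6 is
  # fixation-locked
  expect_equal(s$voluntary_fixation$onset, 170)
  expect_equal(s$inhibitory_gate$onset, 170)
  expect_equal(s$peripheral_inhibition$onset, 170)
  expect_equal(s$voluntary_preparation$onset, -1000 + 170)
  expect_error(input_schedule(worked_anti_trial(), ablations = "not_an_input"),
               "unknown input")
})

test_that("initial bank states match the trial-start description", {
  p <- field_params()
  bank <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  x <- node_positions(p)
  v <- bank$v
  expect_equal(max(v$automated_fixation), 6)
  expect_equal(max(v$voluntary_fixation), 6)
  expect_true(all(v$inhibitory_gate == -8)) # uniform wall
  # peripheral inhibition spares the fovea and is at full depth at the
  # saccade sites (independent scalar evaluation of the notch)
  expect_equal(v$peripheral_inhibition[x == 0], 0)
  expect_equal(v$peripheral_inhibition[x == 2.5],
               -8 * (1 - exp(-2.5^2 / (2 * 0.6^2))), tolerance = 1e-12)
  expect_lt(abs(v$peripheral_inhibition[x == 2.5] + 8), 0.002)
  expect_true(all(v$visual_transient == 0))
  expect_true(all(v$automated_motor == 0))
  expect_true(all(v$voluntary_motor == 0))
  expect_true(all(v$voluntary_preparation == 0))
})

test_that("sign discipline and caps hold along the whole trial", {
  p <- field_params()
  bank <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  excit <- c("visual_transient", "automated_motor", "automated_fixation",
             "voluntary_motor", "voluntary_fixation", "voluntary_preparation")
  inhib <- c("inhibitory_gate", "peripheral_inhibition")
  caps <- c(visual_transient = 8, automated_motor = 6,
            automated_fixation = 6, voluntary_fixation = 6,
            voluntary_preparation = 4, inhibitory_gate = 8,
            peripheral_inhibition = 8)
  for (t in seq(-999, 400)) {
    bank <- update_input_bank(bank, t)
    if (t %% 50 != 0) next # spot-check every 50 ms
    for (nm in excit) expect_true(all(bank$v[[nm]] >= 0))
    for (nm in inhib) expect_true(all(bank$v[[nm]] <= 0))
    for (nm in names(caps)) {
      expect_lte(max(abs(bank$v[[nm]])), caps[[nm]] + 1e-9)
    }
  }
})

test_that("the visual transient bursts and fades on schedule", {
  p <- field_params()
  bank0 <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  x <- node_positions(p)
  b <- advance_bank(bank0, -1000, 50, p)
  expect_true(all(b$v$visual_transient == 0)) # afferent delay
  b <- advance_bank(b, 50, 100, p)
  # peak after the 50-ms rise: k(0) * 0.15 * 50, independent accumulation
  expect_equal(b$v$visual_transient[x == 2.5], 1.05 * 0.15 * 50,
               tolerance = 1e-9)
  b2 <- advance_bank(b, 100, 130, p)
  expect_lt(max(b2$v$visual_transient), max(b$v$visual_transient)) # fading
  b3 <- advance_bank(b2, 130, 250, p)
  expect_true(all(b3$v$visual_transient == 0)) # fully decayed
})

test_that("fixation inputs fade from their event-locked onsets", {
  p <- field_params()
  bank0 <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  x <- node_positions(p)
  # automated fixation: gap starts at -200, delay 60 => first decrement
  # lands at -139
  b <- advance_bank(bank0, -1000, -140, p)
  expect_equal(b$v$automated_fixation[x == 0], 6)
  b <- advance_bank(b, -140, -139, p)
  expect_equal(b$v$automated_fixation[x == 0], 6 - 1.05 * 0.10,
               tolerance = 1e-12)
  # fully faded well before the stimulus: 6 / (1.05 * 0.10) ~ 57 steps
  b <- advance_bank(b, -139, -70, p)
  expect_true(all(b$v$automated_fixation == 0))
  # voluntary fixation decays in unison with the voluntary motor onset and
  # reaches zero after ~57 further steps (literal increment accumulation)
  b <- advance_bank(b, -70, 170, p)
  expect_equal(b$v$voluntary_fixation[x == 0], 6)
  b <- advance_bank(b, 170, 170 + 58, p)
  expect_true(all(b$v$voluntary_fixation == 0))
})

test_that("voluntary preparation peaks exactly at stimulus onset and holds", {
  p <- field_params()
  bank0 <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  x <- node_positions(p)
  b <- advance_bank(bank0, -1000, 0, p)
  expect_equal(b$v$voluntary_preparation[x == 2.5], 4, tolerance = 1e-9)
  expect_equal(b$v$voluntary_preparation[x == -2.5], 4, tolerance = 1e-9)
  # symmetric about fixation
  expect_equal(b$v$voluntary_preparation,
               b$v$voluntary_preparation[mirror_nodes(p)], tolerance = 1e-12)
  b2 <- advance_bank(b, 0, 120, p)
  expect_equal(max(b2$v$voluntary_preparation), 4, tolerance = 1e-9)
})

test_that("the voluntary motor input rises without bound at the goal", {
  p <- field_params()
  bank0 <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  x <- node_positions(p)
  b <- advance_bank(bank0, -1000, 370, p)
  # 200 ms of unbounded rise at 15%: 1.05 * 0.15 * 200 (literal increment accumulation)
  expect_equal(b$v$voluntary_motor[x == -2.5], 1.05 * 0.15 * 200,
               tolerance = 1e-9)
  expect_equal(b$v$voluntary_motor[x == -2.5], 31.5, tolerance = 1e-9)
  expect_equal(b$v$voluntary_motor[x == 2.5], 31.5 * exp(-5^2 / (2 * 0.6^2)),
               tolerance = 1e-9)
})

test_that("gate opening is local and clamped; peripheral release is uniform", {
  p <- field_params()
  bank0 <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  x <- node_positions(p)
  b <- advance_bank(bank0, -1000, 220, p)
  g <- b$v$inhibitory_gate
  expect_equal(g[x == -2.5], max(-8, -8 + 1.05 * 0.10 * 50), tolerance = 1e-9)
  expect_true(all(g <= 0))
  expect_equal(g[x == 2.5], -8, tolerance = 1e-6) # far side stays walled
  # peripheral release: all peripheral nodes rise by the same amount
  pi0 <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  pi0 <- advance_bank(pi0, -1000, 170, p)$v$peripheral_inhibition
  pi1 <- b$v$peripheral_inhibition
  lifted <- pi1 - pi0
  periph <- abs(x) > 2 # nodes where the clamp has not engaged
  expect_equal(max(lifted[periph]), min(lifted[periph]), tolerance = 1e-9)
  expect_equal(lifted[x == 2.5], 1.05 * 0.10 * 50, tolerance = 1e-9)
  expect_true(all(pi1 <= 0))
})

test_that("an anti bank is the pro bank with inputs 4 and 7 mirrored", {
  p <- field_params()
  m <- mirror_nodes(p)
  b_pro <- advance_bank(new_input_bank(worked_anti_trial("pro"),
                                       trial_timeline(), p), -1000, 250, p)
  b_anti <- advance_bank(new_input_bank(worked_anti_trial("anti"),
                                        trial_timeline(), p), -1000, 250, p)
  expect_equal(b_anti$v$voluntary_motor, b_pro$v$voluntary_motor[m])
  expect_equal(b_anti$v$inhibitory_gate, b_pro$v$inhibitory_gate[m])
  same <- setdiff(names(b_pro$v), c("voluntary_motor", "inhibitory_gate"))
  for (nm in same) expect_identical(b_anti$v[[nm]], b_pro$v[[nm]])
})

test_that("crosstalk subtracts the flipped voluntary vector and clamps", {
  p <- field_params()
  n <- p$n_nodes
  x <- node_positions(p)
  vm <- numeric(n); am <- numeric(n)
  am[x == 2.5] <- 4
  vm[x == -2.5] <- 8 # flipped lands on +2.5
  expect_equal(apply_crosstalk(vm, am, 0.25, p)[x == 2.5], 4 - 2)
  am[x == 2.5] <- 1
  expect_equal(apply_crosstalk(vm, am, 0.25, p)[x == 2.5], 0) # clamped
  expect_identical(apply_crosstalk(numeric(n), am, 0.25, p), am) # vm zero
})

test_that("summation is the plain elementwise sum and is linear", {
  p <- field_params()
  bank <- new_input_bank(worked_anti_trial(), trial_timeline(), p)
  manual <- Reduce(`+`, bank$v)
  expect_identical(sum_inputs(bank), manual)
  # a +6 fixation peak against the -8 gate wall: -2 at the centre
  x <- node_positions(p)
  expect_equal(sum_inputs(bank)[x == 0],
               6 + 6 + 0 - 8 + 0, tolerance = 1e-9)
})

test_that("ablation freezes inputs at their initial value", {
  p <- field_params()
  bank <- new_input_bank(worked_anti_trial(), trial_timeline(), p,
                         ablations = c("automated_motor",
                                       "automated_fixation"))
  b <- advance_bank(bank, -1000, 300, p)
  expect_true(all(b$v$automated_motor == 0)) # rises-from-zero: never appears
  expect_equal(max(b$v$automated_fixation), 6) # starts-at-max: frozen there
})
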