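---
title: "A dynamic neural field model of saccadic action selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic neural field model of saccadic action selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`saccfield` simulates how sensory, automated, voluntary and inhibitory
signals, converging on the retinotopic motor map of the intermediate superior
colliculus (SCi), compete to select saccadic eye movements in the pro- and
anti-saccade tasks. This vignette is the package's own account of the model,
its assumptions, the choices made where the design was genuinely open, and
what the simulations do and do not show.

## The field model

Horizontal visual space is represented by a one-dimensional field of
`n_nodes = 100` nodes covering 10 mm of SCi (`dx = 0.1` mm per node), from
-5 mm (far left) through 0 (the fovea, node 50) to +5 mm (far right). The
field is periodic: distances are measured on a ring, which avoids boundary
artefacts.

Each node `i` carries an internal state `u_i` (a membrane-potential-like
quantity) and an output activity `a_i = 1 / (1 + exp(-beta * u_i))` with
`beta = 0.09`. The state evolves by leaky integration of an external
contribution `c_ext` (the sum of the eight component inputs) and an internal
contribution `c_int = W a`:

```
u(t + dt) = (1 - dt/tau) u(t) + (dt/tau) * (c_ext + c_int),
```

with `dt = 1` ms and `tau = 4` ms. The lateral weight matrix `W` is a
circulant Gaussian (`sigma = 0.85` mm, amplitude 74.7) shifted down by 80%
of its maximum and scaled by `dx`: proximal nodes excite each other, distal
nodes inhibit each other, implementing competition between mutually
exclusive saccade plans. Every trial starts with `u = -30` everywhere; the
resting field is approximately self-consistent at that level.

A saccade is triggered the first time the output activity at any
*non-central* node reaches 0.7; the saccade lands at that node and the
saccadic reaction time (SRT) is the time from stimulus onset to the
crossing. "Non-central" is not quantified in the behavioural description of
the model; we exclude nodes within 1.0 mm of the fovea
(`fixation_exclusion_radius`, configurable), which covers the fixation
input's Gaussian (width 0.6 mm) while leaving the +-2.5 mm saccade sites
eligible. If several nodes cross simultaneously the most active wins, with
exact ties resolved towards the smaller eccentricity and then leftwards; the
baseline experiment never needs this rule, but the contract is total.

## The eight component inputs

All inputs share a fixed Gaussian spatial profile `k` (width
`input_gamma = 0.6` mm, amplitude `input_amp = 1.05`) centred on the input's
locus, and piecewise-linear dynamics: after an onset delay the input's value
changes by `k_i * RoR * dt` per step (RoR, rate of response, a fraction per
ms), towards a cap (MaxVal) or towards zero. Rising inputs are capped
profile-wise — node `i` saturates at `MaxVal * k_i / input_amp` — so a
saturated input keeps its Gaussian shape. We also evaluated the more literal
node-wise clamp (`min(value_i, MaxVal)`); it broadens the motor bumps over
time, overshoots the error rates and leaves hundreds of anti-saccade trials
in unresolvable stalemates (no saccade within the window), which contradicts
the requirement that every trial produce a saccade, so the profile-shaped
ceiling is used.

The trial timeline is the gap paradigm: fixation is acquired at -1000 ms,
the fixation point disappears at -200 ms (the gap), the stimulus appears at
0 ms at +-2.5 mm, and simulation ends at 600 ms. The pre-gap fixation
duration is not behaviourally constrained; it only sets the
voluntary-preparation ramp slope. The inputs:

1. **Visual transient** (onset 50 ms after the stimulus, RoR 15%, MaxVal 8,
   at the stimulus): a brief sensory burst; rises for 50 ms, then fades at
   half its RoR to zero.
2. **Automated motor** (onset 60 ms, RoR 4/6/8%, MaxVal 4/6/8, at the
   stimulus in *both* tasks): the practiced, stimulus-triggered motor
   command; rises to its cap and holds until the saccade.
3. **Automated fixation** (onset 60 ms after fixation offset, RoR 10%,
   MaxVal 6, at the fovea): stimulus-dependent fixation activity; at its cap
   until the gap, then fades to zero.
4. **Voluntary motor** (onset delay 140/155/170 ms, RoR 5/10/15%, no cap, at
   the *goal*: the stimulus on pro trials, its mirror on anti trials): the
   internally initiated command; rises without bound until the saccade.
5. **Voluntary fixation** (RoR 10%, MaxVal 4/6/8, at the fovea): internally
   sustained fixation; at its cap from trial start, decaying from the
   voluntary onset.
6. **Voluntary preparation** (onset relative to fixation acquisition, MaxVal
   4/6/8, two peaks at +-2.5 mm): anticipatory build-up over both possible
   stimulus locations; its RoR is derived from its MaxVal so both peaks
   reach the cap exactly at the expected stimulus onset, then hold.
7. **Inhibitory gate** (RoR 5/10/15%, MaxVal 4/6/8): a uniform wall of
   inhibition at depth -MaxVal across the entire field (fovea included);
   from the voluntary onset a local Gaussian opening centred on the goal is
   carved out, clamped at zero per node.
8. **Peripheral inhibition** (RoR 5/10/15%, MaxVal 4/6/8): global inhibition
   sparing the fovea through a smooth complement-of-Gaussian notch
   (`-MaxVal * (1 - k0_i / input_amp)`); from the voluntary onset the whole
   field is released uniformly at `input_amp * RoR` per ms, clamped at zero
   per node. A hard foveal cutoff was considered and rejected in favour of
   the smooth notch to avoid edge artefacts; at the saccade sites the two
   are numerically indistinguishable.

Inputs 4, 5, 7 and 8 share one onset delay per trial (a common internal
drive); input 6 is locked to fixation acquisition with the same delay value.
Inputs 1-6 are non-negative everywhere at all times, inputs 7-8
non-positive.

## Discretisation conventions

Two single-millisecond conventions needed fixing and are stated here because
they are invisible in the continuous description:

* Within each iteration the eight input vectors are advanced to the new time
  point first, then the field update consumes them together with the
  *current* activity (`c_int = W a(t)`); threshold detection happens on the
  updated activity at the new time. The alternative (inputs lagging the
  update by one step) shifts every SRT by exactly +1 ms and nothing else.
* An input with onset time `T` has value `k * RoR * (t - T)` at time `t`:
  the first nonzero increment lands one step after `T`.

The batched engine evaluates the closed forms of the piecewise-linear input
dynamics directly; the pure-R reference engine applies the literal per-step
increments. The two are equivalent by construction (linear ramps with
order-preserving clamps) and the equivalence is asserted to 1e-10 on full
state trajectories in the test suite.

## The deterministic experiment

Nothing in the model is random. Variability is injected by a factorial
design: ten attributes (the shared onset delay; RoR and/or MaxVal of inputs
2, 4, 5, 6, 7, 8) each take one of three values, crossed with the two tasks:
`3^10 * 2 = 118,098` unique trials, every one reproducible bit-for-bit. The
stimulus is always presented at +2.5 mm; the field is mirror-symmetric (the
test suite asserts that a left-stimulus run mirrors the right-stimulus run
exactly), so the left-side grid would be redundant.

Saccades are classified by task, direction and latency: anticipatory
(< 90 ms; the baseline model produces none), express (90-138 ms, both edges
inclusive; 138 is a multiple of the 6-ms histogram bin), and regular
latency. Pro-saccades split into express/regular correct; anti-saccades into
correct anti-saccades (never split by latency) and express/regular direction
errors. Express saccades arise before the earliest voluntary onset (140 ms),
so the set of settings that yields an express saccade is *identical* in the
two tasks and the express-pro and express-error counts are equal by
construction — an exact structural identity of the baseline model, not a
tuned outcome.

## Analyses

The behavioural statistics mirror the human analyses: per-type counts,
percentages (per-task denominators), medians, means, standard deviations
(n-1) and skewness (adjusted Fisher-Pearson; the estimator is a choice —
the source table does not name one, so skewness is treated as a soft
cross-check only); 6-ms SRT histograms; per-attribute effect measures
(large-minus-small median shift, Cohen's d against the behaviour's overall
SD, Kruskal-Wallis across the three settings); chi-square goodness-of-fit
of the setting proportions within each saccade type; and the anti-saccade
difference curve (cumulative % correct minus cumulative % error) with its
*voluntary override time*: the first bin after the curve's global minimum
that rises by at least one percentage point over its predecessor. The
override rule is applied on the 6-ms bin grid (the per-ms reading is
available via `bin_ms = 1`); medians of even-sized groups are the mean of
the central order statistics.

## Post-hoc manipulations

1. **Ablation**: an input is removed by forcing its RoR to zero — inputs
   that rise from zero never appear; inputs that start at strength are
   frozen there. Removing the automated motor input abolishes direction
   errors; removing the visual transient as well makes the two tasks
   identical to the millisecond, a strong internal consistency check of the
   engine (asserted exactly in the tests).
2. **Intentional state**: a task-dependent strategy bias emulated by pure
   post-selection — dropping pro trials with large caps, and anti trials
   with small caps, of the voluntary fixation, inhibitory gate and
   peripheral inhibition inputs. For the combined filter a trial is dropped
   when *any* of the three caps is extreme; the any/all reading is
   ambiguous in the source, but the all-reading is arithmetically
   inconsistent with the published surviving express rate, so "any" is the
   default and "all" remains available behind `rule = "all"`.
3. **Crosstalk**: at every step 25% of the mirrored voluntary motor vector
   is subtracted from the automated motor vector (clamped at zero) before
   summation — a response-inhibition instruction that grows with the
   voluntary command. It is a no-op before the voluntary onset, so express
   counts are provably unchanged; it selectively removes late (> 200 ms)
   direction errors, quantified by the early (140-199 ms) to late
   (200-259 ms) regular-error count ratio.

## Performance and problem sizes

The full experiment demands ~10^12 floating-point operations naively, so the
production engine (C++) batches trials: the lateral term is one BLAS matrix
product per time step across all still-active trials, finished trials are
compacted out at their saccade (early termination is exact: the first
crossing of a full-length trajectory equals the production SRT, asserted in
tests), and the pre-stimulus epoch — which depends only on the onset delay
and the four initial-strength caps — is shared across the grid as 243 unique
pre-stimulus configurations. A full 118,098-trial run takes on the order of
a minute on one CPU; results are independent of the batch size. The unit
tests exercise the step-by-step reference engine on small trial samples and
the full grid only in the acceptance suite.

## What the simulations show — and what they do not

The model reproduces the qualitative architecture of human behaviour in the
gap paradigm: bimodal pro-saccade latencies, slower and more variable
correct anti-saccades, express and regular direction errors with distinct
causes, and the selective effects of preparation and inhibition settings on
saccade selection. It is not a fit to any individual's data: inputs are
conceptual signal components, not firing rates; the three-level factorial
variability is a probe of the mechanism, not an estimate of biological
parameter distributions; corrective saccades after errors, post-saccade
input restoration, two-dimensional map geometry and stop-signal behaviour
are out of scope. Reproduction of the published numbers is faithful to
within a histogram bin on latencies and about one percentage point on
rates; the residual differences (the model here produces ~6.3% express
saccades against the published 7.03%, with a corresponding shortfall in the
filtered express rate and the crosstalk ratio) trace to sub-millisecond
conventions of the original implementation that the verbal description does
not pin down, and are documented rather than tuned away.
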