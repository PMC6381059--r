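# Full-grid simulations are deterministic but take ~1.5 min each; they are
# computed once per test session and shared across test files.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (is.null(.run_cache[[key]])) assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

full_grid <- function() cached_run("grid", function() saccade_grid())

baseline_records <- function() {
  cached_run("baseline", function() run_trials(full_grid()))
}

am_ablation_records <- function() {
  cached_run("am_ablation", function() {
    run_trials(full_grid(), ablations = "automated_motor")
  })
}

amvt_ablation_records <- function() {
  cached_run("amvt_ablation", function() {
    run_trials(full_grid(),
               ablations = c("automated_motor", "visual_transient"))
  })
}

crosstalk_records <- function() {
  cached_run("crosstalk", function() run_trials(full_grid(), crosstalk = 0.25))
}

# a small spread of settings across both tasks and all levels, used by the
# engine-equivalence and symmetry tests
sample_settings <- function(n = 8, seed = 42) {
  g <- full_grid()
  set.seed(seed)
  g[sort(sample(nrow(g), n)), ]
}
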