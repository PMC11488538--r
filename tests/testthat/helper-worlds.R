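# Shared fixtures, built in code and memoised across test files.

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .world_cache))
    assign(key, force(expr), envir = .world_cache)
  get(key, envir = .world_cache)
}

fixture_set <- function() memo("set", build_stimulus_set(seed = 0))

fixture_schedule <- function() {
  memo("schedule", build_session_schedule(fixture_set(), seed = 0))
}

# short schedule (4 reps) for cheaper simulations where 12 trials are not
# part of the contract under test
fixture_schedule4 <- function() {
  memo("schedule4",
       build_session_schedule(fixture_set(), n_reps = 4, n_natural = 5,
                              seed = 0))
}

# 24-unit two-state world over the full battery, 12 reps
small_world <- function() {
  memo("small_world", {
    set <- fixture_set(); sch <- fixture_schedule()
    pop <- sample_population(24, seed = 7)
    wake <- simulate_session_spikes(pop, set, sch, "wake", seed = 8)
    anes <- simulate_session_spikes(pop, set, sch, "anesthesia", seed = 9)
    list(set = set, schedule = sch, pop = pop, wake = wake, anes = anes,
         tw = extract_rate_tensor(wake, sch),
         ta = extract_rate_tensor(anes, sch))
  })
}

# hand-built rate-only tensor: values [units x sounds x reps]
toy_tensor <- function(rates3d, sound_ids = seq_len(dim(rates3d)[2]),
                       durations = rep(0.2, dim(rates3d)[2])) {
  d <- dim(rates3d)
  soundstates:::new_response_tensor(
    array(rates3d, c(d, 1)), bin_s = NA_real_, window = c(-0.3, NA),
    baseline_window = c(-0.3, 0), unit_ids = seq_len(d[1]),
    sound_ids = as.integer(sound_ids),
    durations = stats::setNames(durations, sound_ids), rate_only = TRUE)
}

# nearest pure-tone grid frequency
nearest_grid <- function(f) {
  g <- pure_tone_frequencies()
  g[vapply(f, function(x) which.min(abs(log2(g / x))), 0L)]
}
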