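## End-to-end pipeline: protocol -> simulate -> metrics -> match -> decode ->
## state space, with a single seed and a structured report.

#' Default pipeline configuration
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_units Population size (default 60 for a quick run; 150 matches
#'   the desk-scale benchmark).
#' @param class_probs Remodeling class probabilities (see
#'   [sample_population()]).
#' @param silenced_frac Fraction of units silent under anesthesia.
#' @param n_reps,block_size Schedule parameters.
#' @param n_splits Decoder train/test splits.
#' @param mode Decoding mode (`"time_averaged"` is the cheap default).
#' @param match_percentile,match_margin Matching parameters.
#' @param jitter_sd Template jitter between states.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, n_units = 60,
                           class_probs = c(24, 34, 35, 36) / 129,
                           silenced_frac = 0.4,
                           n_reps = 12, block_size = 30,
                           n_splits = 50, mode = "time_averaged",
                           match_percentile = 95, match_margin = 0.2,
                           jitter_sd = 0.05) {
  cfg <- list(seed = as.integer(seed), n_units = n_units,
              class_probs = class_probs, silenced_frac = silenced_frac,
              n_reps = n_reps, block_size = block_size,
              n_splits = n_splits, mode = mode,
              match_percentile = match_percentile,
              match_margin = match_margin, jitter_sd = jitter_sd)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (abs(sum(cfg$class_probs) - 1) > 1e-9)
    stop_invalid("class_probs must sum to 1")
  if (any(cfg$class_probs < 0) || cfg$silenced_frac < 0 ||
      cfg$silenced_frac > 1)
    stop_invalid("probabilities must lie in [0, 1]")
  for (f in c("n_units", "n_reps", "block_size", "n_splits"))
    if (cfg[[f]] <= 0) stop_invalid("%s must be positive", f)
  invisible(cfg)
}

#' Run the full two-state analysis pipeline on simulated data
#'
#' Simulates a ground-truth population and both states' spike trains over a
#' full session, then runs every analysis stage: spontaneous rates, evoked
#' modulation, best-frequency recovery, response-change classification,
#' cross-state template matching, same-state and cross-state decoding and the
#' PC-space state classifier. All randomness derives from `config$seed`, so
#' repeated runs are identical.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as CSV/JSON (stimuli, schedule trials, spikes, ground truth, report).
#' @return A report list with per-stage summaries.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
  }
  set <- stage("protocol", build_stimulus_set(seed))
  schedule <- stage("protocol", build_session_schedule(
    set, n_reps = config$n_reps, block_size = config$block_size, seed = seed))
  pop <- stage("simulate", sample_population(
    config$n_units, class_probs = config$class_probs,
    silenced_frac = config$silenced_frac, seed = seed))
  spikes_w <- stage("simulate",
                    simulate_session_spikes(pop, set, schedule, "wake",
                                            seed = seed + 1L))
  spikes_a <- stage("simulate",
                    simulate_session_spikes(pop, set, schedule, "anesthesia",
                                            seed = seed + 2L))
  tens_w <- stage("metrics", extract_rate_tensor(spikes_w, schedule))
  tens_a <- stage("metrics", extract_rate_tensor(spikes_a, schedule))

  spont_w <- spontaneous_rate(spikes_w, schedule)
  spont_a <- spontaneous_rate(spikes_a, schedule)
  curves_w <- tuning_curves(tens_w, set, level_db = 70)
  bf_est <- vapply(seq_len(config$n_units), function(u)
    best_frequency(unit_tuning(curves_w, u), use_abs = TRUE), 0)
  grid <- pure_tone_frequencies()
  bf_true_bin <- grid[vapply(pop$bf_wake, function(f)
    which.min(abs(log2(grid / f))), 0L)]
  strong <- abs(pop$gain_wake) >= 10
  bf_recovery <- mean(bf_est[strong] == bf_true_bin[strong])
  classes <- stage("metrics", classify_population(tens_w, tens_a, set))

  tmpl <- stage("match", generate_templates(pop, jitter_sd = config$jitter_sd,
                                            seed = seed + 3L))
  anes_present <- pop$remodel_class != "silenced"
  match_perf <- if (any(anes_present)) {
    corr <- template_correlation_matrix(tmpl$wake, tmpl$anes[anes_present])
    thr <- chance_threshold(corr, percentile = config$match_percentile)
    match_performance(match_units(corr, thr, margin = config$match_margin))
  } else c(precision = NA_real_, recall = NA_real_, n_accepted = 0)

  same_w <- stage("decode", nn_classify(tens_w, NULL, mode = config$mode,
                                        n_splits = config$n_splits,
                                        seed = seed + 4L))
  same_a <- stage("decode", nn_classify(tens_a, NULL, mode = config$mode,
                                        n_splits = config$n_splits,
                                        seed = seed + 5L))
  cross <- stage("decode", cross_state_design(tens_w, tens_a,
                                              mode = config$mode,
                                              n_splits = config$n_splits,
                                              seed = seed + 6L))
  ssv <- stage("statespace", sound_state_vectors(tens_w, tens_a))
  proj <- stage("statespace", pca_project(ssv, k = 3))
  svm <- stage("statespace", svm_state_classification(proj, seed = seed + 7L))

  report <- list(
    config = unclass(config),
    population = list(
      n_units = config$n_units,
      class_counts = as.list(table(pop$remodel_class)),
      mean_spont_wake = mean(spont_w), mean_spont_anes = mean(spont_a)),
    metrics = list(bf_recovery_strong_gain = bf_recovery,
                   classified = as.list(table(classes$class))),
    matching = as.list(match_perf),
    decoding = list(same_state_wake = same_w$accuracy,
                    same_state_anes = same_a$accuracy,
                    cross_state = cross$accuracy,
                    chance = 1 / length(same_w$sound_ids)),
    state_space = list(svm_cv_accuracy = svm$cv_accuracy,
                       explained_variance = proj$explained_variance))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stimulus_csv(set, file.path(out_dir, "stimuli.csv"))
    write_schedule_csv(schedule, file.path(out_dir, "schedule.csv"))
    write_spikes_csv(spikes_w, file.path(out_dir, "spikes_wake.csv"))
    write_spikes_csv(spikes_a, file.path(out_dir, "spikes_anesthesia.csv"))
    jsonlite::write_json(pop, file.path(out_dir, "ground_truth.json"),
                         dataframe = "rows", digits = NA)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
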