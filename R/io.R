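## Plain-text persistence: CSV for tables, JSON for structured results.
## Every writer records the seed(s) used so runs can be reproduced.

#' Write a stimulus set to CSV
#'
#' One row per sound; structured parameters (frequencies, bands, sweeps,
#' modulation) are serialized as a JSON string column so the table
#' round-trips losslessly.
#'
#' @param set A `stimulus_set`.
#' @param path Output CSV path.
#' @export
write_stimulus_csv <- function(set, path) {
  params <- vapply(set$stimuli, function(s) {
    as.character(jsonlite::toJSON(
      s[c("level_db", "freqs", "band", "mod_freq_hz", "sweep",
          "temporal_shape")], auto_unbox = FALSE, digits = NA, null = "null"))
  }, "")
  df <- cbind(set$table, params_json = params, seed = set$seed)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read a stimulus set from CSV
#' @param path CSV written by [write_stimulus_csv()].
#' @return A `stimulus_set`.
#' @export
read_stimulus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stimuli <- lapply(seq_len(nrow(df)), function(i) {
    p <- jsonlite::fromJSON(df$params_json[i], simplifyVector = TRUE)
    sound_stimulus(df$category[i], df$duration_s[i],
                   level_db = as.numeric(p$level_db),
                   freqs = as.numeric(p$freqs),
                   band = if (!is.null(p$band)) matrix(unlist(p$band), ncol = 2),
                   direction = df$direction[i],
                   mod_freq_hz = if (length(p$mod_freq_hz) &&
                                     !is.na(p$mod_freq_hz[1]))
                     as.numeric(p$mod_freq_hz) else NA,
                   sweep = if (!is.null(p$sweep)) as.numeric(p$sweep),
                   temporal_shape = if (!is.null(p$temporal_shape))
                     as.numeric(p$temporal_shape),
                   sound_id = df$sound_id[i])
  })
  structure(list(stimuli = stimuli,
                 table = df[c("sound_id", "category", "duration_s",
                              "level_db", "direction")],
                 seed = df$seed[1]),
            class = "stimulus_set")
}

#' Write a session schedule's trial table to CSV
#' @param schedule A `session_schedule`.
#' @param path Output CSV path.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$trials, path, row.names = FALSE)
}

#' Read a schedule trial table from CSV
#' @param path CSV written by [write_schedule_csv()].
#' @return The trial `data.frame` (`trial_index`, `sound_id`, `onset_s`,
#'   `segment_index`).
#' @export
read_schedule_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write spike trains to CSV (unit_id, state, spike_time_s)
#' @param trains A `spike_trains` object.
#' @param path Output CSV path.
#' @export
write_spikes_csv <- function(trains, path) {
  n <- vapply(trains$trains, length, 0L)
  df <- data.frame(unit_id = rep(trains$unit_ids, n),
                   state = trains$state,
                   spike_time_s = unlist(trains$trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read spike trains from CSV
#' @param path CSV written by [write_spikes_csv()].
#' @param duration_s Recording duration (defaults to the last spike time).
#' @return A `spike_trains` object.
#' @export
read_spikes_csv <- function(path, duration_s = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sp <- split(df$spike_time_s, df$unit_id)
  ids <- as.integer(names(sp))
  o <- order(ids)
  structure(list(trains = lapply(sp[o], sort), unit_ids = ids[o],
                 state = df$state[1],
                 duration_s = duration_s %||% max(df$spike_time_s),
                 seed = NA_integer_),
            class = "spike_trains")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
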