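## Per-unit response metrics.
##
## Responses are extracted per trial as 10-ms binned firing-rate histograms
## in a [-0.3, 1.0] s window around sound onset; the mean rate over the
## prestimulus period (-0.3 to 0 s) is subtracted for each trial.

new_response_tensor <- function(values, bin_s, window, baseline_window,
                                unit_ids, sound_ids, durations,
                                rate_only = FALSE, baseline = NULL) {
  structure(list(values = values, bin_s = bin_s, window = window,
                 baseline_window = baseline_window, unit_ids = unit_ids,
                 sound_ids = sound_ids, durations = durations,
                 rate_only = rate_only, baseline = baseline),
            class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("response_tensor: %d units x %d sounds x %d trials x %d bins%s\n",
              d[1], d[2], d[3], d[4],
              if (x$rate_only) " (time-averaged rates)" else ""))
  invisible(x)
}

# spike trains as a plain named list of numeric vectors
as_train_list <- function(spikes) {
  if (inherits(spikes, "spike_trains")) spikes$trains
  else if (is.numeric(spikes)) list(spikes)
  else spikes
}

# counts of sorted spike times within [a, b) for many intervals at once
count_in <- function(st, a, b) {
  findInterval(b, st, left.open = TRUE) - findInterval(a, st, left.open = TRUE)
}

#' Extract the binned response tensor
#'
#' Builds per-trial peri-stimulus histograms at `bin_s` resolution over
#' `window` (seconds relative to onset) for every unit and short-sound trial,
#' in units of spk/s, and subtracts each trial's mean baseline rate
#' (`baseline_window`). Trials whose window extends beyond the recorded
#' interval are dropped with a warning (all repetitions of the affected sound
#' are dropped to keep the tensor rectangular).
#'
#' @param spikes A `spike_trains` object or named list of sorted spike-time
#'   vectors.
#' @param schedule A `session_schedule`.
#' @param bin_s Bin width in seconds (default 0.010).
#' @param window Response window around onset (default `c(-0.3, 1)`).
#' @param baseline_window Baseline window (default `c(-0.3, 0)`).
#' @return A `response_tensor` (units x sounds x trials x bins).
#' @export
extract_response_tensor <- function(spikes, schedule, bin_s = 0.010,
                                    window = c(-0.3, 1),
                                    baseline_window = c(-0.3, 0)) {
  trains <- as_train_list(spikes)
  rec_end <- if (inherits(spikes, "spike_trains")) spikes$duration_s
             else session_duration(schedule)
  tr <- schedule$trials
  ok <- tr$onset_s + window[1] >= 0 & tr$onset_s + window[2] <= rec_end
  if (!all(ok)) {
    bad_sounds <- unique(tr$sound_id[!ok])
    warning(sprintf("dropping %d sound(s) with trials outside the recording",
                    length(bad_sounds)))
    tr <- tr[!tr$sound_id %in% bad_sounds, ]
  }
  onset_by_sound <- split(tr$onset_s, tr$sound_id)
  reps <- vapply(onset_by_sound, length, 0L)
  if (length(unique(reps)) != 1)
    stop_invalid("unequal trial counts across sounds (%s)",
                 paste(range(reps), collapse = "-"))
  n_reps <- reps[[1]]
  sound_ids <- as.integer(names(onset_by_sound))
  edges <- seq(window[1], window[2], by = bin_s)
  n_bins <- length(edges) - 1L
  centers <- edges[-1] - bin_s / 2
  base_bins <- which(centers > baseline_window[1] &
                     centers <= baseline_window[2])
  n_units <- length(trains)
  vals <- array(0, c(n_units, length(sound_ids), n_reps, n_bins))
  # trial order matching [sound, rep] slices
  s_of <- rep(seq_along(sound_ids), each = n_reps)
  r_of <- rep(seq_len(n_reps), length(sound_ids))
  onsets_all <- unlist(onset_by_sound, use.names = FALSE)
  qv <- as.numeric(outer(edges, onsets_all, "+"))
  o <- order(qv)
  for (u in seq_len(n_units)) {
    st <- trains[[u]]
    fi <- integer(length(qv))
    fi[o] <- findInterval(qv[o], st, left.open = TRUE)
    fi <- matrix(fi, nrow = length(edges))
    cnt <- fi[-1, , drop = FALSE] - fi[-length(edges), , drop = FALSE]
    rate <- cnt / bin_s
    rate <- sweep(rate, 2, colMeans(rate[base_bins, , drop = FALSE]))
    for (t in seq_along(onsets_all))
      vals[u, s_of[t], r_of[t], ] <- rate[, t]
  }
  new_response_tensor(vals, bin_s, window, baseline_window,
                      unit_ids = if (!is.null(names(trains)))
                        as.integer(names(trains)) else seq_len(n_units),
                      sound_ids = sound_ids,
                      durations = schedule$durations[as.character(sound_ids)])
}

#' Extract time-averaged (rate) responses
#'
#' Cheap single-number summary per trial: mean firing rate during the sound
#' (`[0, duration)`) minus the mean rate in the `baseline_s` window before
#' onset. Returns a `response_tensor` with a single time bin, flagged
#' `rate_only`; all downstream functions accept it wherever time-averaged
#' responses suffice.
#'
#' @inheritParams extract_response_tensor
#' @param baseline_s Baseline window length before onset (default 0.3 s).
#' @return A `response_tensor` with one bin; its `baseline` field holds the
#'   per-trial raw baseline rates (units x sounds x trials).
#' @export
extract_rate_tensor <- function(spikes, schedule, baseline_s = 0.3) {
  trains <- as_train_list(spikes)
  tr <- schedule$trials
  onset_by_sound <- split(tr$onset_s, tr$sound_id)
  n_reps <- length(onset_by_sound[[1]])
  sound_ids <- as.integer(names(onset_by_sound))
  durs <- schedule$durations[as.character(sound_ids)]
  n_units <- length(trains)
  vals <- array(0, c(n_units, length(sound_ids), n_reps, 1))
  base <- array(0, c(n_units, length(sound_ids), n_reps))
  s_of <- rep(seq_along(sound_ids), each = n_reps)
  r_of <- rep(seq_len(n_reps), length(sound_ids))
  onsets_all <- unlist(onset_by_sound, use.names = FALSE)
  dur_all <- durs[s_of]
  for (u in seq_len(n_units)) {
    st <- trains[[u]]
    # three sorted query vectors: baseline start, onset, offset
    c0 <- findInterval(onsets_all - baseline_s, st)
    c1 <- findInterval(onsets_all, st)
    c2i <- order(onsets_all + dur_all)
    c2 <- integer(length(onsets_all))
    c2[c2i] <- findInterval((onsets_all + dur_all)[c2i], st)
    ev <- (c2 - c1) / dur_all
    bl <- (c1 - c0) / baseline_s
    vals[cbind(u, s_of, r_of, 1L)] <- ev - bl
    base[cbind(u, s_of, r_of)] <- bl
  }
  new_response_tensor(vals, bin_s = NA_real_, window = c(-baseline_s, NA),
                      baseline_window = c(-baseline_s, 0),
                      unit_ids = if (!is.null(names(trains)))
                        as.integer(names(trains)) else seq_len(n_units),
                      sound_ids = sound_ids, durations = durs,
                      rate_only = TRUE, baseline = base)
}

#' Time-averaged response rates from a tensor
#'
#' Collapses the time axis to the mean baseline-subtracted rate during each
#' sound's presentation.
#'
#' @param tensor A `response_tensor`.
#' @return 3-d array (units x sounds x trials) of spk/s.
#' @export
response_rates <- function(tensor) {
  stopifnot(inherits(tensor, "response_tensor"))
  d <- dim(tensor$values)
  if (tensor$rate_only) return(array(tensor$values, d[1:3]))
  centers <- seq(tensor$window[1] + tensor$bin_s / 2, tensor$window[2],
                 by = tensor$bin_s)
  out <- array(0, d[1:3])
  for (s in seq_len(d[2])) {
    bins <- which(centers > 0 & centers <= tensor$durations[s])
    out[, s, ] <- apply(tensor$values[, s, , bins, drop = FALSE], c(1, 3), mean)
  }
  out
}

#' Spontaneous firing rate from inter-block intervals
#'
#' Counts spikes in a window of `window_len_s` seconds starting
#' `window_start_offset_s` after the end of each segment (i.e. within each
#' silent gap) and divides by the total window time, `n_gaps *
#' window_len_s` (284 s with the default schedule: 142 gaps x 2 s).
#'
#' @inheritParams extract_response_tensor
#' @param window_start_offset_s Offset of the window after segment end
#'   (default 0.3 s).
#' @param window_len_s Window length (default 2 s).
#' @return Named numeric vector of spontaneous rates (spk/s), one per unit.
#' @export
spontaneous_rate <- function(spikes, schedule, window_start_offset_s = 0.3,
                             window_len_s = 2.0) {
  trains <- as_train_list(spikes)
  if (nrow(schedule$gaps) == 0)
    stop_invalid("schedule has no inter-segment gaps")
  if (window_start_offset_s + window_len_s > min(schedule$gaps$duration_s))
    stop_invalid("spontaneous window exceeds gap duration")
  a <- schedule$gaps$start_s + window_start_offset_s
  b <- a + window_len_s
  denom <- nrow(schedule$gaps) * window_len_s
  vapply(trains, function(st) sum(count_in(st, a, b)) / denom, 0)
}

#' Mean sound-evoked firing-rate modulation
#'
#' Average over sounds and trials of the mean baseline-subtracted rate during
#' sound presentation.
#'
#' @param tensor A `response_tensor`.
#' @return Numeric vector, one value (spk/s) per unit.
#' @export
evoked_modulation <- function(tensor) {
  rates <- response_rates(tensor)
  apply(rates, 1, mean)
}

#' Trial-to-trial response reliability
#'
#' For one unit, each trial's binned responses to all sounds are concatenated
#' into a sound-response vector; reliability is the average Pearson
#' correlation over all unordered trial pairs. Pairs involving a
#' zero-variance vector are excluded (with a message).
#'
#' @param tensor A `response_tensor`.
#' @param unit Unit index (row of the tensor).
#' @return Mean pairwise correlation in \[-1, 1\].
#' @export
reliability <- function(tensor, unit) {
  v <- tensor$values[unit, , , , drop = FALSE]
  d <- dim(v)
  if (d[3] < 2) stop_invalid("reliability needs >= 2 trials")
  # trial j's vector concatenates all sounds' bins
  M <- sapply(seq_len(d[3]), function(r) as.numeric(v[1, , r, ]))
  sds <- apply(M, 2, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) < d[3])
    message(sprintf("reliability: excluded %d zero-variance trial vector(s)",
                    d[3] - length(keep)))
  if (length(keep) < 2) return(NA_real_)
  cm <- stats::cor(M[, keep])
  mean(cm[upper.tri(cm)])
}

#' Pure-tone tuning curves for all units
#'
#' Mean time-averaged response per pure-tone frequency at one sound level.
#'
#' @param tensor A `response_tensor` covering the full battery.
#' @param set The `stimulus_set` that produced the schedule.
#' @param level_db Pure-tone level to use (50 or 70).
#' @return List with `frequencies` (kHz) and `response` (units x frequencies
#'   matrix of mean baseline-subtracted rates).
#' @export
tuning_curves <- function(tensor, set, level_db = 70) {
  tab <- set$table
  ids <- tab$sound_id[tab$category == "pure_tone" & tab$level_db == level_db]
  idx <- match(ids, tensor$sound_ids)
  if (anyNA(idx)) stop_invalid("tensor does not cover the pure-tone battery")
  freqs <- vapply(set$stimuli[ids], function(s) s$freqs[1], 0)
  o <- order(freqs)
  rates <- response_rates(tensor)
  resp <- apply(rates[, idx[o], , drop = FALSE], c(1, 2), mean)
  list(frequencies = freqs[o],
       response = matrix(resp, nrow = dim(rates)[1]))
}

#' Extract one unit's tuning curve
#'
#' @param curves Output of [tuning_curves()].
#' @param unit Unit index (row).
#' @return List with `frequencies` and `response` for that unit.
#' @export
unit_tuning <- function(curves, unit) {
  list(frequencies = curves$frequencies, response = curves$response[unit, ])
}

#' Best frequency of a tuning curve
#'
#' Frequency with the maximal mean response; ties are broken toward the
#' lowest frequency.
#'
#' @param tuning List with `frequencies` and `response` (one unit's curve).
#' @param use_abs If `TRUE`, maximize the absolute response (so suppressed
#'   units get a best frequency too); default `FALSE` (signed maximum).
#' @return Best frequency in kHz.
#' @export
best_frequency <- function(tuning, use_abs = FALSE) {
  r <- if (use_abs) abs(tuning$response) else tuning$response
  if (!length(r)) stop_invalid("empty tuning curve")
  tuning$frequencies[which.max(r)]
}

#' Tuning half-width in octaves
#'
#' Width of the frequency tuning curve at half its maximal absolute response:
#' starting from the peak of `|r|`, the nearest half-maximum crossings above
#' and below are located by linear interpolation of `|r|` against log2
#' frequency, and the half-width is `log2(f_above / f_below)`. If `|r|` never
#' falls to half maximum before a grid edge, the crossing is censored at the
#' edge frequency and flagged in the `"censored"` attribute.
#'
#' @param tuning List with `frequencies` and `response`.
#' @return Half-width in octaves, with attribute `censored` (logical
#'   `c(low, high)`).
#' @export
half_width_octaves <- function(tuning) {
  r <- abs(tuning$response)
  f <- tuning$frequencies
  m <- which.max(r)
  if (r[m] <= 0) stop_invalid("half-width undefined: peak response is zero")
  half <- r[m] / 2
  cens <- c(low = FALSE, high = FALSE)
  # upward crossing
  i <- m
  while (i < length(r) && r[i + 1] >= half) i <- i + 1
  if (i == length(r)) { f_hi <- f[i]; cens["high"] <- TRUE } else {
    x <- log2(f[i:(i + 1)])
    f_hi <- 2^(x[1] + (x[2] - x[1]) * (r[i] - half) / (r[i] - r[i + 1]))
  }
  # downward crossing
  i <- m
  while (i > 1 && r[i - 1] >= half) i <- i - 1
  if (i == 1) { f_lo <- f[i]; cens["low"] <- TRUE } else {
    x <- log2(f[i:(i - 1)])
    f_lo <- 2^(x[1] + (x[2] - x[1]) * (r[i] - half) / (r[i] - r[i - 1]))
  }
  structure(log2(f_hi / f_lo), censored = cens)
}

#' Intensity threshold from an up-ramped tone response
#'
#' Given the trial-averaged baseline-subtracted PSTH (bins at `t >= 0`) of a
#' sound linearly ramped from 50 to 70 dB SPL over `ramp_dur_s`, finds the
#' first bin in which the response exceeds twice the SD of the spontaneous
#' (baseline) bin distribution and maps its time to a level via
#' `50 + 20 * t / ramp_dur_s`. A zero spontaneous SD is replaced by a small
#' floor; a response that never crosses is flagged unresponsive.
#'
#' @param ramp_response Numeric vector: trial-averaged baseline-subtracted
#'   rates in consecutive `bin_s` bins from sound onset.
#' @param spont_bins Numeric vector of baseline-bin rates (the null sample).
#' @param bin_s Bin width in seconds (default 0.010).
#' @param ramp_dur_s Ramp duration in seconds (default 0.5).
#' @param level_range Ramp endpoint levels (default `c(50, 70)` dB SPL).
#' @param sd_floor Minimal SD used when the baseline SD is zero.
#' @return Threshold in dB SPL, or `NA` with attribute `unresponsive = TRUE`
#'   if the response never crosses.
#' @export
intensity_threshold <- function(ramp_response, spont_bins, bin_s = 0.010,
                                ramp_dur_s = 0.5, level_range = c(50, 70),
                                sd_floor = 1e-6) {
  sd_s <- max(stats::sd(spont_bins), sd_floor, na.rm = TRUE)
  cross <- which(ramp_response > 2 * sd_s)
  if (!length(cross))
    return(structure(NA_real_, unresponsive = TRUE))
  t_cross <- (cross[1] - 1) * bin_s   # left edge of the crossing bin
  lev <- level_range[1] +
    diff(level_range) * min(t_cross, ramp_dur_s) / ramp_dur_s
  structure(lev, unresponsive = FALSE)
}

#' Classify the cross-state response change of one unit at best frequency
#'
#' Applies two-sided Mann-Whitney U tests at level `alpha`: each state's
#' per-trial responses are first tested against the baseline null sample;
#' if neither state differs from baseline the unit is `nonresponsive`; if
#' both differ with opposite response signs it is a `sign_change`; otherwise
#' the two states' responses are compared directly and the unit is labeled
#' `decrease` (significantly lower firing under anesthesia), `increase`, or
#' `no_change`.
#'
#' @param wake_resp,anes_resp Per-trial baseline-subtracted responses (spk/s)
#'   at best frequency (>= 3 trials each).
#' @param wake_baseline,anes_baseline Null samples: pooled baseline-bin (or
#'   mean-centred baseline-rate) values for the same trials.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @return One of `"decrease"`, `"increase"`, `"sign_change"`, `"no_change"`,
#'   `"nonresponsive"`.
#' @export
classify_response_change <- function(wake_resp, anes_resp,
                                     wake_baseline, anes_baseline,
                                     alpha = 0.05) {
  if (length(wake_resp) < 3 || length(anes_resp) < 3)
    stop_invalid("insufficient data: need >= 3 trials per state")
  test <- function(x, y) {
    if (all(x == 0) && all(y == 0)) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
  sig_w <- test(wake_resp, wake_baseline) < alpha
  sig_a <- test(anes_resp, anes_baseline) < alpha
  if (!sig_w && !sig_a) return("nonresponsive")
  if (sig_w && sig_a &&
      sign(mean(wake_resp)) != sign(mean(anes_resp)) &&
      sign(mean(wake_resp)) != 0 && sign(mean(anes_resp)) != 0)
    return("sign_change")
  p_cross <- test(wake_resp, anes_resp)
  if (p_cross < alpha) {
    if (mean(anes_resp) < mean(wake_resp)) "decrease" else "increase"
  } else "no_change"
}

#' Classify response changes for a whole population
#'
#' For every unit, picks the best frequency (largest absolute mean pure-tone
#' response at `level_db` in whichever state responds more strongly), then
#' applies [classify_response_change()] to the per-trial responses at that
#' frequency.
#'
#' @param wake_tensor,anes_tensor Neuron-aligned `response_tensor`s.
#' @param set The `stimulus_set`.
#' @param level_db Pure-tone level at which to classify (default 70).
#' @param alpha Significance level.
#' @return `data.frame` with `unit_id`, `class` and `bf_khz`.
#' @export
classify_population <- function(wake_tensor, anes_tensor, set, level_db = 70,
                                alpha = 0.05) {
  tab <- set$table
  ids <- tab$sound_id[tab$category == "pure_tone" & tab$level_db == level_db]
  freqs <- vapply(set$stimuli[ids], function(s) s$freqs[1], 0)
  o <- order(freqs); ids <- ids[o]; freqs <- freqs[o]
  idx <- match(ids, wake_tensor$sound_ids)
  rw <- response_rates(wake_tensor)
  ra <- response_rates(anes_tensor)
  n_units <- dim(rw)[1]
  base_null <- function(tensor, u, s_idx) {
    if (!is.null(tensor$baseline)) {
      b <- tensor$baseline[u, s_idx, ]
      b - mean(b)
    } else {
      centers <- seq(tensor$window[1] + tensor$bin_s / 2, tensor$window[2],
                     by = tensor$bin_s)
      bb <- which(centers > tensor$baseline_window[1] &
                  centers <= tensor$baseline_window[2])
      as.numeric(tensor$values[u, s_idx, , bb])
    }
  }
  out <- character(n_units); bfs <- numeric(n_units)
  for (u in seq_len(n_units)) {
    mw <- abs(apply(rw[u, idx, , drop = FALSE], 2, mean))
    ma <- abs(apply(ra[u, idx, , drop = FALSE], 2, mean))
    k <- if (max(ma) > max(mw)) which.max(ma) else which.max(mw)
    s_idx <- idx[k]
    out[u] <- classify_response_change(
      rw[u, s_idx, ], ra[u, s_idx, ],
      base_null(wake_tensor, u, s_idx), base_null(anes_tensor, u, s_idx),
      alpha = alpha)
    bfs[u] <- freqs[k]
  }
  data.frame(unit_id = wake_tensor$unit_ids, class = out, bf_khz = bfs,
             stringsAsFactors = FALSE)
}
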