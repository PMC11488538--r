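## Two-state population simulator.
##
## Ground-truth neurons carry per-state tuning parameters (spontaneous rate,
## best frequency, half-width in octaves, signed peak gain, intensity
## threshold, latency). Tuning is Gaussian in log2-frequency, parameterized
## directly by the half-width at half-maximum so the half-width estimator has
## an analytic target; the intensity threshold is a soft (~5 dB) sigmoid gate.
## Spiking is inhomogeneous Poisson with rates rectified at zero.

REMODEL_CLASSES <- c("decrease", "increase", "sign_change", "no_change")

#' Sample a ground-truth two-state neuron population
#'
#' Draws per-unit wake and anesthesia tuning parameters with state-dependent
#' remodeling. A fraction `silenced_frac` of units is completely silent under
#' anesthesia (zero spontaneous rate and zero gain); the remaining units are
#' assigned a remodeling class by a multinomial draw from `class_probs`:
#' `decrease` / `increase` of response magnitude at best frequency,
#' `sign_change` (opposite response signs across states) or `no_change`.
#' Default class probabilities are (24, 34, 35, 36)/129. Wake spontaneous
#' rates span roughly 0-100 spk/s (log-normal); anesthesia spontaneous rates
#' are strictly reduced. Best frequencies are essentially preserved across
#' states; anesthesia tuning is slightly narrower and thresholds slightly
#' higher.
#'
#' @param n_units Number of units (>= 0).
#' @param class_probs Probability vector over the four remodeling classes
#'   (summing to 1 within 1e-9), in the order decrease, increase, sign_change,
#'   no_change.
#' @param silenced_frac Probability that a unit is completely silent under
#'   anesthesia (default 0.4, within the observed 32-47% range).
#' @param n_recordings Number of recording sessions the units are split
#'   across (default 7).
#' @param seed Integer seed.
#' @return A `data.frame` of class `neuron_population`, one row per unit:
#'   `unit_id`, `recording_id`, `remodel_class`, and per-state columns
#'   `spont_wake`/`spont_anes` (spk/s), `bf_wake`/`bf_anes` (kHz),
#'   `hw_wake`/`hw_anes` (octaves), `gain_wake`/`gain_anes` (signed spk/s at
#'   peak), `thr_wake`/`thr_anes` (dB SPL), `latency_s`.
#' @export
sample_population <- function(n_units,
                              class_probs = c(24, 34, 35, 36) / 129,
                              silenced_frac = 0.4,
                              n_recordings = 7,
                              seed = 0L) {
  if (n_units < 0) stop_invalid("n_units must be non-negative")
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop_invalid("class_probs must sum to 1")
  if (length(class_probs) != 4)
    stop_invalid("class_probs must have 4 entries (%s)",
                 paste(REMODEL_CLASSES, collapse = ", "))
  local_seed(seed, {
    silenced <- stats::runif(n_units) < silenced_frac
    cls <- ifelse(silenced, "silenced",
                  sample(REMODEL_CLASSES, n_units, replace = TRUE,
                         prob = class_probs))
    recording_id <- 1 + (seq_len(n_units) - 1) %% n_recordings

    spont_w <- pmin(stats::rlnorm(n_units, log(4), 1.2), 100)
    # sign-change units need enough wake baseline for suppression to show
    sc <- cls == "sign_change"
    spont_w[sc] <- stats::runif(sum(sc), 25, 70)
    spont_a <- spont_w * stats::runif(n_units, 0.05, 0.5)
    spont_a[silenced] <- 0

    # best frequencies on the pure-tone probe grid (the recovery target is
    # the nearest grid frequency); anesthesia BF essentially preserved
    bf_w <- sample(pure_tone_frequencies(), n_units, replace = TRUE)
    bf_a <- pmin(60, pmax(2, bf_w * 2^stats::rnorm(n_units, 0, 0.05)))
    hw_w <- stats::runif(n_units, 0.4, 0.8)
    hw_a <- hw_w * stats::runif(n_units, 0.6, 0.95)
    thr_w <- stats::runif(n_units, 45, 60)
    thr_a <- thr_w + stats::runif(n_units, 0, 5)

    g <- stats::runif(n_units, 40, 90)
    small <- stats::runif(n_units, 0.05, 0.3)
    gain_w <- gain_a <- g
    gain_a[cls == "decrease"] <- (g * small)[cls == "decrease"]
    gain_w[cls == "increase"] <- (g * small)[cls == "increase"]
    # most sign changes: suppressed in wake, excited under anesthesia
    flip_dir <- stats::runif(n_units) < 0.85
    gain_w[sc & flip_dir] <- -g[sc & flip_dir]
    gain_a[sc & !flip_dir] <- -g[sc & !flip_dir]
    gain_a[silenced] <- 0

    structure(data.frame(
      unit_id = seq_len(n_units), recording_id = recording_id,
      remodel_class = cls,
      spont_wake = spont_w, spont_anes = spont_a,
      bf_wake = bf_w, bf_anes = bf_a,
      hw_wake = hw_w, hw_anes = hw_a,
      gain_wake = gain_w, gain_anes = gain_a,
      thr_wake = thr_w, thr_anes = thr_a,
      latency_s = 0.005,
      stringsAsFactors = FALSE),
      class = c("neuron_population", "data.frame"),
      seed = as.integer(seed))
  })
}

#' Construct a population with disjoint responsive subsets across states
#'
#' Builds a ground-truth population in which each unit responds in exactly one
#' state: half are responsive only in wakefulness (silent under anesthesia)
#' and half only under anesthesia (zero wake gain). This is the "full
#' neuron-subset remodeling" construction under which cross-state decoding
#' must collapse to chance while same-state decoding stays high.
#'
#' @inheritParams sample_population
#' @return A `neuron_population`.
#' @export
disjoint_state_population <- function(n_units, n_recordings = 7, seed = 0L) {
  pop <- sample_population(n_units, silenced_frac = 0,
                           n_recordings = n_recordings, seed = seed)
  half <- seq_len(n_units) <= n_units / 2
  pop$remodel_class <- ifelse(half, "silenced", "increase")
  pop$gain_wake <- abs(pop$gain_wake)
  pop$gain_anes <- abs(pop$gain_anes)
  pop$gain_anes[half] <- 0
  pop$spont_anes[half] <- 0
  pop$gain_wake[!half] <- 0
  pop
}

state_params <- function(neuron, state) {
  state <- match.arg(state, c("wake", "anesthesia"))
  suf <- if (state == "wake") "wake" else "anes"
  list(spont = neuron[[paste0("spont_", suf)]],
       bf = neuron[[paste0("bf_", suf)]],
       hw = neuron[[paste0("hw_", suf)]],
       gain = neuron[[paste0("gain_", suf)]],
       thr = neuron[[paste0("thr_", suf)]],
       latency = neuron$latency_s)
}

# Gaussian tuning in log2-frequency. `hw` is the FULL tuning half-width in
# octaves, log2(f_above/f_below) between the two half-maximum frequencies
# (the quantity the half-width estimator reports), so the factor reaches 1/2
# at hw/2 octaves either side of bf.
tuning_factor <- function(f, bf, hw) 2^(-(2 * octaves(f, bf) / hw)^2)

# frequency drive factor for arbitrary spectral content at bin times `t`
freq_factor_at <- function(p, stim, t) {
  ff <- rep(0, length(t))
  if (!is.null(stim$band)) {
    for (bi in seq_len(nrow(stim$band))) {
      lo <- stim$band[bi, 1]; hi <- stim$band[bi, 2]
      fac <- if (p$bf >= lo && p$bf <= hi) 1 else
        tuning_factor(if (p$bf < lo) lo else hi, p$bf, p$hw)
      ff <- pmax(ff, fac)
    }
  }
  if (!is.null(stim$sweep)) {
    ff <- pmax(ff, tuning_factor(stimulus_freqs_at(stim, t), p$bf, p$hw))
  } else if (length(stim$freqs)) {
    ff <- pmax(ff, max(tuning_factor(stim$freqs, p$bf, p$hw)))
  }
  ff
}

# signed driven-rate profile (spk/s, spont excluded) on a `dt` grid over the
# sound duration
drive_profile <- function(p, stim, dt = 0.01) {
  t <- seq(dt / 2, stim$duration_s, by = dt)
  p$gain * freq_factor_at(p, stim, t) *
    level_gate(stimulus_level(stim, t), p$thr) *
    cos_ramp(t, stim$duration_s) * stimulus_temporal_mod(stim, t)
}

#' Firing-rate time course of a simulated neuron for one stimulus
#'
#' Evaluates the ground-truth rate model: spontaneous rate plus the driven
#' component (peak gain scaled by Gaussian log2-frequency tuning, the soft
#' intensity-threshold gate and the stimulus temporal envelope), rectified at
#' zero. At the unit's best frequency and a suprathreshold static level the
#' mid-sound plateau rate equals `spont + gain` (rectified); half a tuning
#' half-width away in frequency the driven component halves.
#'
#' @param neuron One row of a `neuron_population`.
#' @param stim A `sound_stimulus`.
#' @param state `"wake"` or `"anesthesia"`.
#' @param time_step_s Time step of the returned series (seconds).
#' @return Numeric vector of non-negative rates (spk/s) over the sound
#'   duration, one value per time bin.
#' @export
rate_timecourse <- function(neuron, stim, state, time_step_s = 0.001) {
  p <- state_params(neuron, state)
  pmax(0, p$spont + drive_profile(p, stim, dt = time_step_s))
}

#' Draw an inhomogeneous Poisson spike train from a rate series
#'
#' Bin-wise Poisson sampling: the spike count in each bin is Poisson with
#' mean `rate * time_step_s` and spike times are placed uniformly within
#' their bin, so counts in any window are Poisson with mean equal to the
#' integral of the rate.
#'
#' @param rate_series Non-negative rate values (spk/s), one per bin.
#' @param time_step_s Bin width in seconds.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param t0 Time of the first bin's left edge (seconds).
#' @return Sorted numeric vector of spike times in seconds.
#' @export
generate_spikes <- function(rate_series, time_step_s, seed = NULL, t0 = 0) {
  if (any(rate_series < 0)) stop_invalid("rates must be non-negative")
  draw <- function() {
    counts <- stats::rpois(length(rate_series), rate_series * time_step_s)
    bins <- rep(seq_along(rate_series) - 1L, counts)
    sort(t0 + (bins + stats::runif(length(bins))) * time_step_s)
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Simulate spike trains for a whole session in one state
#'
#' Generates, for every unit, an inhomogeneous-Poisson spike train over the
#' full session: a homogeneous spontaneous process over the session plus, for
#' each trial, the driven rate profile of the presented sound (superposition
#' for positive drive; exact thinning of spontaneous spikes where the
#' rectified rate falls below the spontaneous rate).
#'
#' @param population A `neuron_population`.
#' @param set The `stimulus_set` used by the schedule.
#' @param schedule A `session_schedule`.
#' @param state `"wake"` or `"anesthesia"`.
#' @param seed Integer seed.
#' @param dt Rate-profile resolution in seconds (default 0.01).
#' @return An object of class `spike_trains`: list with `trains` (named list
#'   of sorted spike-time vectors, one per unit), `unit_ids`, `state`,
#'   `duration_s` and `seed`.
#' @export
simulate_session_spikes <- function(population, set, schedule, state,
                                    seed = 0L, dt = 0.01) {
  state <- match.arg(state, c("wake", "anesthesia"))
  T_total <- session_duration(schedule)
  trials_by_sound <- split(schedule$trials$onset_s, schedule$trials$sound_id)
  stim_by_id <- set$stimuli
  local_seed(seed, {
    trains <- vector("list", nrow(population))
    for (u in seq_len(nrow(population))) {
      p <- state_params(population[u, ], state)
      sp <- if (p$spont > 0)
        sort(stats::runif(stats::rpois(1, p$spont * T_total), 0, T_total))
        else numeric()
      keep_mask <- rep(TRUE, length(sp))
      added <- vector("list", length(trials_by_sound))
      if (p$gain != 0) {
        for (k in seq_along(trials_by_sound)) {
          sid <- as.integer(names(trials_by_sound)[k])
          stim <- stim_by_id[[sid]]
          d <- drive_profile(p, stim, dt)
          # sounds far outside the tuning band contribute < 0.05 spk/s and
          # are skipped (< 0.02 expected spikes over all 12 trials)
          if (max(abs(d)) < 0.05) next
          r <- pmax(0, p$spont + d)
          add_rate <- pmax(0, r - p$spont)
          onsets <- trials_by_sound[[k]] + p$latency
          ntr <- length(onsets); nb <- length(d)
          if (any(add_rate > 0)) {
            counts <- stats::rpois(nb * ntr, rep(add_rate * dt, ntr))
            if (sum(counts) > 0) {
              bin_idx <- rep.int(rep(seq_len(nb) - 1L, ntr), counts)
              trial_idx <- rep.int(rep(seq_len(ntr), each = nb), counts)
              added[[k]] <- onsets[trial_idx] +
                (bin_idx + stats::runif(length(bin_idx))) * dt
            }
          }
          if (p$spont > 0 && any(r < p$spont)) {
            keep <- pmin(r, p$spont) / p$spont
            # one sortedness-checked search per sound, not per trial
            qi <- findInterval(as.numeric(rbind(onsets, onsets + nb * dt)), sp)
            for (k2 in seq_len(ntr)) {
              i1 <- qi[2 * k2 - 1L] + 1L; i2 <- qi[2 * k2]
              if (i2 < i1) next
              idx <- i1:i2
              b <- pmin(nb, floor((sp[idx] - onsets[k2]) / dt) + 1L)
              drop <- stats::runif(length(idx)) > keep[b]
              keep_mask[idx[drop]] <- FALSE
            }
          }
        }
      }
      trains[[u]] <- sort(c(sp[keep_mask], unlist(added)))
    }
    names(trains) <- as.character(population$unit_id)
    structure(list(trains = trains, unit_ids = population$unit_id,
                   state = state, duration_s = T_total,
                   seed = as.integer(seed)),
              class = "spike_trains")
  })
}

#' @export
print.spike_trains <- function(x, ...) {
  n <- vapply(x$trains, length, 0L)
  cat("spike_trains:", length(x$trains), "units,", x$state, "state,",
      sum(n), "spikes over", round(x$duration_s), "s\n")
  invisible(x)
}

# one random multi-lobe spike waveform (channels x samples, in uV)
random_template_waveform <- function(n_channels, n_samples) {
  A <- stats::runif(1, 80, 300)
  t <- seq_len(n_samples)
  t0 <- n_samples %/% 3
  tau1 <- stats::runif(1, 2, 6)
  tau2 <- stats::runif(1, 6, 18)
  tau0 <- stats::runif(1, 3, 9)
  b1 <- stats::runif(1, 0.15, 0.5)
  b0 <- stats::runif(1, 0, 0.3)
  d1 <- stats::runif(1, 4, 14)
  shape <- -exp(-((t - t0) / tau1)^2) + b1 * exp(-((t - t0 - d1) / tau2)^2) +
    b0 * exp(-((t - t0 - d1 / 2) / tau0)^2)
  shape <- shape / max(abs(shape))
  peak_ch <- sample(seq(2, n_channels - 1), 1)
  lam_up <- stats::runif(1, 1, 4); lam_dn <- stats::runif(1, 1, 4)
  ch <- seq_len(n_channels)
  prof <- ifelse(ch <= peak_ch, exp(-(peak_ch - ch) / lam_up),
                 exp(-(ch - peak_ch) / lam_dn))
  list(waveform = A * outer(prof, shape), peak_channel = peak_ch)
}

#' Generate per-state spike templates for a population
#'
#' Each unit receives a random multi-lobe base waveform (channels x samples,
#' in microvolts) used as its wake template; the anesthesia template is the
#' same waveform perturbed by a multiplicative amplitude factor and smooth
#' additive shape noise of relative magnitude `jitter_sd`, so that true-pair
#' correlation exceeds cross-unit correlations in expectation.
#'
#' @param population A `neuron_population`.
#' @param jitter_sd Relative amplitude/shape jitter (>= 0); 0 gives identical
#'   wake and anesthesia templates.
#' @param seed Integer seed.
#' @param n_channels,n_samples Template geometry (default 20 x 61).
#' @return List with elements `wake` and `anes`, each a list of templates:
#'   `list(unit_id, recording_id, waveform, peak_channel)`.
#' @export
generate_templates <- function(population, jitter_sd = 0.05, seed = 0L,
                               n_channels = 20, n_samples = 61) {
  if (jitter_sd < 0) stop_invalid("jitter_sd must be >= 0")
  local_seed(seed, {
    wake <- anes <- vector("list", nrow(population))
    for (u in seq_len(nrow(population))) {
      base <- random_template_waveform(n_channels, n_samples)
      A <- max(abs(base$waveform))
      scale <- 1 + stats::rnorm(1, 0, jitter_sd)
      noise <- matrix(stats::rnorm(n_channels * n_samples), n_channels)
      noise <- t(apply(noise, 1, function(r)
        as.numeric(stats::filter(r, rep(1 / 5, 5), sides = 2, circular = TRUE))))
      wa <- base$waveform * scale + jitter_sd * A * 0.5 * noise
      wake[[u]] <- list(unit_id = population$unit_id[u],
                        recording_id = population$recording_id[u],
                        waveform = base$waveform,
                        peak_channel = base$peak_channel)
      anes[[u]] <- list(unit_id = population$unit_id[u],
                        recording_id = population$recording_id[u],
                        waveform = wa,
                        peak_channel = which.max(apply(abs(wa), 1, max)))
    }
    list(wake = wake, anes = anes)
  })
}

#' Synthesize an extracellular voltage snippet
#'
#' Additive model: Gaussian background noise plus each unit's template
#' waveform inserted at its spike times. Spikes whose waveform would extend
#' beyond the trace are clipped with a warning.
#'
#' @param trains List of spike-time vectors (seconds), one per template.
#' @param templates List of templates aligned with `trains` (each with a
#'   `waveform` channels-x-samples matrix).
#' @param noise_sd Background noise SD in microvolts.
#' @param duration_s Trace duration in seconds.
#' @param sample_rate Sampling rate in Hz (default 30000).
#' @param seed Optional integer seed.
#' @return Matrix (channels x samples) of voltage in microvolts.
#' @export
synthesize_voltage <- function(trains, templates, noise_sd, duration_s,
                               sample_rate = 30000, seed = NULL) {
  if (sample_rate <= 0) stop_invalid("sample_rate must be positive")
  n <- round(duration_s * sample_rate)
  n_ch <- if (length(templates)) nrow(templates[[1]]$waveform) else 1
  build <- function() {
    trace <- matrix(stats::rnorm(n_ch * n, 0, noise_sd), n_ch, n)
    clipped <- 0L
    for (k in seq_along(trains)) {
      w <- templates[[k]]$waveform
      ns <- ncol(w)
      for (ts in trains[[k]]) {
        i0 <- round(ts * sample_rate) - ns %/% 3
        j1 <- max(1L, i0 + 1L); j2 <- min(n, i0 + ns)
        if (j2 < j1) next
        if (j2 - j1 + 1L < ns) clipped <- clipped + 1L
        trace[, j1:j2] <- trace[, j1:j2] + w[, (j1 - i0):(j2 - i0), drop = FALSE]
      }
    }
    if (clipped > 0)
      warning(sprintf("%d spike waveform(s) clipped at trace boundaries",
                      clipped))
    trace
  }
  if (is.null(seed)) build() else local_seed(seed, build())
}
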