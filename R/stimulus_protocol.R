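## Stimulus battery and session schedule construction.
##
## The battery holds 307 short (< 0.5 s) sounds in 8 categories with fixed
## per-category counts; a session plays each sound 12 times in random order in
## 123 blocks of 30 trials (1-s onset spacing), with 20 long "natural" segments
## interleaved between blocks and silent gaps (>= 3 s) between all segments.

#' Frequencies of the pure-tone battery
#'
#' Fourteen frequencies logarithmically spaced between 2 and 60 kHz; the grid
#' on which frequency tuning is probed.
#'
#' @return Numeric vector of 14 frequencies in kHz; first element 2, last 60,
#'   all consecutive ratios equal to `(60/2)^(1/13)`.
#' @export
#' @examples
#' pure_tone_frequencies()
pure_tone_frequencies <- function() {
  geom_seq(2, 60, 14)
}

#' Construct a single sound stimulus
#'
#' Low-level constructor for one element of the stimulus battery. Most users
#' should call [build_stimulus_set()] instead.
#'
#' @param category One of `"pure_tone"`, `"ramp"`, `"chord"`, `"chirp"`,
#'   `"white_noise"`, `"am"`, `"complex"`, `"decomposition"`.
#' @param duration_s Sound duration in seconds, in (0, 0.5].
#' @param level_db Sound pressure level in dB SPL; a scalar for statically
#'   leveled sounds or a length-2 `c(start, end)` trajectory for intensity
#'   ramps.
#' @param freqs Component frequencies in kHz (may be empty for pure noises).
#' @param band Optional frequency band(s) in kHz: a length-2 vector or a
#'   two-column matrix (one row per band) for band-limited noises.
#' @param direction `"up"`, `"down"` or `"none"` (ramps and chirps).
#' @param mod_freq_hz Sinusoidal amplitude-modulation frequency in Hz (AM
#'   sounds only).
#' @param sweep Length-2 vector of chirp sweep endpoints in kHz.
#' @param temporal_shape Optional fixed temporal envelope (10-ms grid, values
#'   in \[0, 1\]) for complex/decomposition sounds.
#' @param sound_id Integer identifier.
#' @return An object of class `sound_stimulus`.
#' @export
sound_stimulus <- function(category, duration_s, level_db, freqs = numeric(),
                           band = NULL, direction = "none", mod_freq_hz = NA,
                           sweep = NULL, temporal_shape = NULL, sound_id = NA) {
  categories <- c("pure_tone", "ramp", "chord", "chirp", "white_noise",
                  "am", "complex", "decomposition")
  if (!category %in% categories)
    stop_invalid("unsupported stimulus category: %s", category)
  if (duration_s <= 0 || duration_s > 0.5)
    stop_invalid("duration_s must lie in (0, 0.5], got %g", duration_s)
  if (length(freqs) && (any(freqs < 2) || any(freqs > 80)))
    stop_invalid("component frequencies must lie in [2, 80] kHz")
  if (any(level_db < 50) || any(level_db > 70))
    stop_invalid("level_db must lie within [50, 70] dB SPL")
  if (!is.null(band)) band <- matrix(band, ncol = 2, byrow = FALSE)
  structure(list(sound_id = sound_id, category = category,
                 duration_s = duration_s, level_db = level_db,
                 freqs = freqs, band = band, direction = direction,
                 mod_freq_hz = mod_freq_hz, sweep = sweep,
                 temporal_shape = temporal_shape),
            class = "sound_stimulus")
}

# smooth positive random envelope on a 10-ms grid, used for complex sounds
random_envelope <- function(n) {
  x <- stats::runif(n + 8)
  x <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  x <- as.numeric(x[!is.na(x)])[seq_len(n)]
  x <- x - min(x)
  if (max(x) > 0) x <- x / max(x)
  0.2 + 0.8 * x
}

#' Build the 307-sound stimulus battery
#'
#' Constructs the full short-sound battery: 28 pure tones (14 log-spaced
#' frequencies between 2 and 60 kHz at 50 and 70 dB SPL), 26 intensity ramps
#' (the 13 frequencies below 50 kHz, up and down between 50 and 70 dB),
#' 48 chords (2-4 summed 70-dB tones from low/medium/high/broad/harmonic
#' groups), 20 frequency chirps, 30 band-passed white noises, 48 sinusoidally
#' amplitude-modulated sounds (6 modulation frequencies between 4 and 160 Hz
#' by 8 carriers), 60 complex sounds (15 bases, forward/reversed, 50/70 dB)
#' and 47 decomposition snippets of four of the complex bases.
#'
#' Counts and parameter ranges are fixed; the seed only controls free
#' parameters (exact chord/noise frequency draws, complex-sound envelopes).
#'
#' @param seed Integer seed controlling the free parameter draws.
#' @return An object of class `stimulus_set`: a list with `stimuli` (list of
#'   [sound_stimulus()] objects, ordered by `sound_id` 1..307), `table` (a
#'   summary `data.frame`) and `seed`.
#' @export
#' @examples
#' set <- build_stimulus_set(seed = 0)
#' table(set$table$category)
build_stimulus_set <- function(seed = 0L) {
  local_seed(seed, {
    stimuli <- list()
    add <- function(s) stimuli[[length(stimuli) + 1L]] <<- s
    pt <- pure_tone_frequencies()

    ## 28 pure tones: 14 frequencies x {50, 70} dB
    for (f in pt) for (L in c(50, 70))
      add(sound_stimulus("pure_tone", 0.3, L, freqs = f))

    ## 26 intensity ramps: 13 frequencies (<= 50 kHz), up and down, 0.5 s
    for (f in pt[pt <= 50]) for (d in c("up", "down"))
      add(sound_stimulus("ramp", 0.5,
                         if (d == "up") c(50, 70) else c(70, 50),
                         freqs = f, direction = d))

    ## 48 chords: 2-4 summed 70-dB tones
    chord_group <- function(n, lo, hi) {
      replicate(n, sort(exp(stats::runif(sample(2:4, 1), log(lo), log(hi)))),
                simplify = FALSE)
    }
    chord_freqs <- c(chord_group(11, 2, 8),     # low
                     chord_group(11, 8, 25),    # medium
                     chord_group(11, 25, 60),   # high
                     chord_group(10, 2, 60),    # broad
                     replicate(5, {             # harmonic series
                       f0 <- exp(stats::runif(1, log(2), log(10)))
                       k <- sample(2:4, 1)
                       pmin(f0 * seq_len(k + 1), 80)
                     }, simplify = FALSE))
    for (fr in chord_freqs)
      add(sound_stimulus("chord", 0.2, 70, freqs = fr))

    ## 20 chirps: 10 fixed 6-12 kHz sweeps of varied duration, 10 varied-range
    ## 500-ms sweeps within 4-50 kHz, all at 50 dB
    for (dur in c(0.025, 0.05, 0.1, 0.2, 0.4)) for (d in c("up", "down"))
      add(sound_stimulus("chirp", dur, 50,
                         sweep = if (d == "up") c(6, 12) else c(12, 6),
                         direction = d))
    for (i in 1:5) {
      lo <- exp(stats::runif(1, log(4), log(20)))
      hi <- min(50, lo * 2^stats::runif(1, 1, 2.5))
      for (d in c("up", "down"))
        add(sound_stimulus("chirp", 0.5, 50,
                           sweep = if (d == "up") c(lo, hi) else c(hi, lo),
                           direction = d))
    }

    ## 30 white noises: 6 broadband (2 static levels + 4 intensity-ramped),
    ## 14 band-filtered, 10 two-band ramped sums matching chord frequencies
    for (L in c(50, 70))
      add(sound_stimulus("white_noise", 0.2, L, band = c(2, 80)))
    for (dur in c(0.1, 0.5)) for (d in c("up", "down"))
      add(sound_stimulus("white_noise", dur,
                         if (d == "up") c(50, 70) else c(70, 50),
                         band = c(2, 80), direction = d))
    for (i in 1:14) {
      ctr <- exp(stats::runif(1, log(3), log(55)))
      hbw <- stats::runif(1, 0.25, 1.5)  # half bandwidth in octaves
      add(sound_stimulus("white_noise", 0.2, sample(c(50, 70), 1),
                         band = c(max(2, ctr / 2^hbw), min(80, ctr * 2^hbw))))
    }
    sum_src <- sample(seq_along(chord_freqs), 10)
    for (i in seq_along(sum_src)) {
      ctrs <- chord_freqs[[sum_src[i]]][1:2]
      bnd <- rbind(c(max(2, ctrs[1] - 0.5), min(80, ctrs[1] + 0.5)),
                   c(max(2, ctrs[2] - 0.5), min(80, ctrs[2] + 0.5)))
      d <- if (i %% 2 == 1) "up" else "down"
      add(sound_stimulus("white_noise", 0.5,
                         if (d == "up") c(50, 70) else c(70, 50),
                         band = bnd, direction = d))
    }

    ## 48 AM sounds: 6 modulation frequencies x 8 carriers
    am_carriers <- c(list(pt[7], pt[10]),
                     chord_freqs[sample(seq_along(chord_freqs), 5)],
                     list("broadband"))
    for (fm in c(4, 8, 16, 40, 80, 160)) for (carrier in am_carriers) {
      if (identical(carrier, "broadband"))
        add(sound_stimulus("am", 0.5, 70, band = c(2, 80), mod_freq_hz = fm))
      else
        add(sound_stimulus("am", 0.5, 70, freqs = carrier, mod_freq_hz = fm))
    }

    ## 60 complex sounds: 15 bases x {forward, reversed} x {50, 70} dB
    complex_bases <- replicate(15, {
      k <- sample(3:6, 1)
      list(freqs = sort(exp(stats::runif(k, log(2), log(80)))),
           shape = random_envelope(40))
    }, simplify = FALSE)
    for (b in complex_bases) for (d in c("none", "down")) for (L in c(50, 70))
      add(sound_stimulus("complex", 0.4, L, freqs = b$freqs,
                         direction = if (d == "down") "down" else "none",
                         temporal_shape = if (d == "down") rev(b$shape)
                                          else b$shape))

    ## 47 decomposition sounds: snippets/partial sums of 4 complex bases
    dec_counts <- c(12, 12, 12, 11)
    for (bi in 1:4) {
      b <- complex_bases[[bi]]
      k <- length(b$freqs)
      for (i in seq_len(dec_counts[bi])) {
        comp <- if (i <= k) b$freqs[i]
                else sort(sample(b$freqs, sample(2:k, 1)))
        seg <- b$shape[seq(1 + (i %% 2) * 20, length.out = 20)]
        add(sound_stimulus("decomposition", 0.2, 70, freqs = comp,
                           temporal_shape = seg))
      }
    }

    for (i in seq_along(stimuli)) stimuli[[i]]$sound_id <- i
    tab <- data.frame(
      sound_id = seq_along(stimuli),
      category = vapply(stimuli, `[[`, "", "category"),
      duration_s = vapply(stimuli, `[[`, 0, "duration_s"),
      level_db = vapply(stimuli, function(s) s$level_db[1], 0),
      direction = vapply(stimuli, `[[`, "", "direction"),
      stringsAsFactors = FALSE)
    structure(list(stimuli = stimuli, table = tab, seed = as.integer(seed)),
              class = "stimulus_set")
  })
}

#' Per-category stimulus counts
#'
#' @param set A `stimulus_set`.
#' @return Named integer vector of counts per category.
#' @export
category_counts <- function(set) {
  stopifnot(inherits(set, "stimulus_set"))
  tab <- table(set$table$category)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("stimulus_set:", length(x$stimuli), "sounds (seed", x$seed, ")\n")
  print(category_counts(x))
  invisible(x)
}

#' Instantaneous sound level of a stimulus
#'
#' Returns the dB SPL trajectory of a stimulus at times `t` (seconds from
#' sound onset). Intensity ramps are linear in dB between their endpoint
#' levels; statically leveled sounds are constant. Times outside
#' `[0, duration_s]` return `NA`.
#'
#' @param stim A `sound_stimulus`.
#' @param t Numeric vector of times in seconds from sound onset.
#' @return Numeric vector of levels in dB SPL.
#' @export
stimulus_level <- function(stim, t) {
  L <- stim$level_db
  lev <- if (length(L) == 2) L[1] + (L[2] - L[1]) * t / stim$duration_s
         else rep(L, length(t))
  lev[t < 0 | t > stim$duration_s] <- NA_real_
  lev
}

# instantaneous component frequencies; for chirps, log-interpolated sweep
stimulus_freqs_at <- function(stim, t) {
  if (!is.null(stim$sweep)) {
    exp(log(stim$sweep[1]) +
          (log(stim$sweep[2]) - log(stim$sweep[1])) * t / stim$duration_s)
  } else stim$freqs
}

# fixed temporal modulation in [0, 1]: AM sinusoid, stored envelope, or 1
stimulus_temporal_mod <- function(stim, t) {
  mod <- rep(1, length(t))
  if (!is.na(stim$mod_freq_hz))
    mod <- (1 - cos(2 * pi * stim$mod_freq_hz * t)) / 2
  if (!is.null(stim$temporal_shape)) {
    shp <- stim$temporal_shape
    mod <- mod * stats::approx(seq(0, stim$duration_s, length.out = length(shp)),
                               shp, xout = pmin(pmax(t, 0), stim$duration_s),
                               rule = 2)$y
  }
  mod
}

#' Time-frequency energy envelope of a stimulus
#'
#' Rasterizes a stimulus onto a time-by-frequency grid: linear amplitude
#' (relative to 50 dB SPL) confined to the stimulus band(s) or component
#' frequencies, with 10-ms cosine onset/offset ramps, sinusoidal modulation
#' for AM sounds and the stored envelope for complex sounds. Frequency bins
#' are centred on `freq_grid` values with edges at geometric midpoints.
#'
#' @param stim A `sound_stimulus`.
#' @param time_step_s Time step in seconds (> 0).
#' @param freq_grid Sorted vector of grid frequencies in kHz.
#' @return Matrix (time bins x frequency bins) of non-negative energy.
#' @export
stimulus_envelope <- function(stim, time_step_s, freq_grid) {
  if (time_step_s <= 0) stop_invalid("time_step_s must be > 0")
  if (is.unsorted(freq_grid)) stop_invalid("freq_grid must be sorted")
  if (!inherits(stim, "sound_stimulus"))
    stop_invalid("unsupported stimulus object")
  t <- seq(time_step_s / 2, stim$duration_s, by = time_step_s)
  nf <- length(freq_grid)
  # bin edges at geometric midpoints
  edges <- c(0, sqrt(freq_grid[-nf] * freq_grid[-1]), Inf)
  amp <- 10^((stimulus_level(stim, t) - 50) / 20) *
    cos_ramp(t, stim$duration_s) * stimulus_temporal_mod(stim, t)
  env <- matrix(0, length(t), nf)
  if (!is.null(stim$band)) {
    for (bi in seq_len(nrow(stim$band))) {
      inband <- freq_grid >= stim$band[bi, 1] & freq_grid <= stim$band[bi, 2]
      env[, inband] <- env[, inband] + amp
    }
  }
  if (!is.null(stim$sweep)) {
    fb <- findInterval(stimulus_freqs_at(stim, t), edges)
    env[cbind(seq_along(t), fb)] <- env[cbind(seq_along(t), fb)] + amp
  } else if (length(stim$freqs)) {
    for (f in stim$freqs) {
      fb <- findInterval(f, edges)
      env[, fb] <- env[, fb] + amp
    }
  }
  env
}

#' Build a block-structured session schedule
#'
#' Lays out one presentation of the battery: every short sound is repeated
#' `n_reps` times in a seeded random order, packed into blocks of
#' `block_size` trials with `onset_interval_s` between consecutive onsets;
#' `n_natural` long natural-sound segments are interleaved at distinct
#' randomly chosen inter-block positions, and every pair of consecutive
#' segments is separated by a silent gap of `gap_s` seconds. With the default
#' battery this yields 123 blocks (the last holding 24 trials, since
#' 307 x 12 = 3684 = 122 x 30 + 24), 20 natural segments and 142 gaps.
#'
#' @param set A `stimulus_set`.
#' @param n_reps Repetitions of each short sound (default 12).
#' @param block_size Trials per block (default 30).
#' @param onset_interval_s Seconds between consecutive onsets in a block.
#' @param n_natural Number of interleaved natural segments (default 20:
#'   10 natural sounds played twice each).
#' @param gap_s Silent gap between segments, seconds (>= 3).
#' @param natural_duration_s Duration of each natural segment (default 30 s).
#' @param lead_in_s Silence before the first segment (default 1 s), so the
#'   first trial's baseline window lies inside the recording.
#' @param seed Integer seed for trial order and natural-segment placement.
#' @return An object of class `session_schedule` with elements `trials`
#'   (short-sound trial table: `trial_index`, `sound_id`, `onset_s`,
#'   `segment_index`), `natural` (natural-segment table), `segments`, `gaps`,
#'   `durations` (named by sound id) and `params`.
#' @export
build_session_schedule <- function(set, n_reps = 12, block_size = 30,
                                   onset_interval_s = 1.0, n_natural = 20,
                                   gap_s = 3, natural_duration_s = 30,
                                   lead_in_s = 1.0, seed = 0L) {
  stopifnot(inherits(set, "stimulus_set"))
  if (block_size <= 0) stop_invalid("block_size must be positive")
  if (n_reps <= 0) stop_invalid("n_reps must be positive")
  if (gap_s < 3) stop_invalid("gap_s must be >= 3 s")
  ids <- set$table$sound_id
  local_seed(seed, {
    order_ids <- sample(rep(ids, n_reps))
    n_trials <- length(order_ids)
    n_blocks <- ceiling(n_trials / block_size)
    if (n_natural > 0 && n_natural > n_blocks - 1)
      stop_invalid("n_natural exceeds available inter-block positions")
    nat_after <- if (n_natural > 0) sort(sample(n_blocks - 1, n_natural))
                 else integer()
    nat_ids <- if (n_natural > 0)
      sample(rep(-(seq_len(ceiling(n_natural / 2))), length.out = n_natural))
      else integer()

    seg_kind <- character(); seg_block <- integer()
    ni <- 1L
    for (b in seq_len(n_blocks)) {
      seg_kind <- c(seg_kind, "block"); seg_block <- c(seg_block, b)
      while (ni <= n_natural && !is.na(nat_after[ni]) && nat_after[ni] == b) {
        seg_kind <- c(seg_kind, "natural"); seg_block <- c(seg_block, NA)
        ni <- ni + 1L
      }
    }
    n_seg <- length(seg_kind)

    trials <- list(); naturals <- list()
    seg_start <- seg_end <- numeric(n_seg)
    t0 <- lead_in_s; ti <- 0L; nat_i <- 0L
    for (si in seq_len(n_seg)) {
      seg_start[si] <- t0
      if (seg_kind[si] == "block") {
        b <- seg_block[si]
        idx <- ((b - 1) * block_size + 1):min(b * block_size, n_trials)
        onsets <- t0 + (seq_along(idx) - 1) * onset_interval_s
        trials[[b]] <- data.frame(trial_index = ti + seq_along(idx),
                                  sound_id = order_ids[idx],
                                  onset_s = onsets, segment_index = si)
        ti <- ti + length(idx)
        t0 <- t0 + length(idx) * onset_interval_s
      } else {
        nat_i <- nat_i + 1L
        naturals[[nat_i]] <- data.frame(sound_id = nat_ids[nat_i],
                                        onset_s = t0, segment_index = si)
        t0 <- t0 + natural_duration_s
      }
      seg_end[si] <- t0
      if (si < n_seg) t0 <- t0 + gap_s
    }
    trials <- do.call(rbind, trials)
    naturals <- if (nat_i > 0) do.call(rbind, naturals) else
      data.frame(sound_id = integer(), onset_s = numeric(),
                 segment_index = integer())
    gaps <- if (n_seg > 1)
      data.frame(start_s = seg_end[-n_seg], duration_s = gap_s) else
      data.frame(start_s = numeric(), duration_s = numeric())
    durations <- stats::setNames(set$table$duration_s,
                                 as.character(set$table$sound_id))
    structure(list(
      trials = trials, natural = naturals,
      segments = data.frame(segment_index = seq_len(n_seg), kind = seg_kind,
                            start_s = seg_start, end_s = seg_end),
      gaps = gaps, durations = durations,
      params = list(n_reps = n_reps, block_size = block_size,
                    onset_interval_s = onset_interval_s,
                    n_natural = n_natural, gap_s = gap_s,
                    natural_duration_s = natural_duration_s,
                    seed = as.integer(seed))),
      class = "session_schedule")
  })
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("session_schedule:", nrow(x$trials), "short-sound trials in",
      sum(x$segments$kind == "block"), "blocks,",
      sum(x$segments$kind == "natural"), "natural segments,",
      nrow(x$gaps), "gaps; total", round(max(x$segments$end_s)), "s\n")
  invisible(x)
}

#' Total duration of a session in seconds
#' @param schedule A `session_schedule`.
#' @return Length of the session in seconds (end of the last segment).
#' @export
session_duration <- function(schedule) max(schedule$segments$end_s)
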