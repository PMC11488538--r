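#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so library calls never perturb user-level reproducibility.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Geometric (log-spaced) sequence, exact at both endpoints.
geom_seq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

# log2 frequency distance in octaves
octaves <- function(f, ref) log2(f / ref)

# Soft level gate: ~0 well below threshold, ~1 well above, with a ~5 dB
# transition band (10-90% over ~5.5 dB).
level_gate <- function(level_db, threshold_db) {
  stats::plogis((level_db - threshold_db) / 1.25)
}

# Cosine onset/offset ramp envelope (10 ms by default) evaluated at times `t`
# within a sound of duration `dur`.
cos_ramp <- function(t, dur, ramp_s = 0.010) {
  ramp_s <- min(ramp_s, dur / 2)
  env <- rep(1, length(t))
  on <- t < ramp_s
  off <- t > dur - ramp_s
  env[on] <- 0.5 * (1 - cos(pi * t[on] / ramp_s))
  env[off] <- 0.5 * (1 - cos(pi * (dur - t[off]) / ramp_s))
  env[t < 0 | t > dur] <- 0
  env
}
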