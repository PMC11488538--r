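# Two-state population simulator.

test_that("sample_population respects class probabilities and invariants", {
  expect_error(sample_population(-1), "non-negative")
  expect_error(sample_population(10, class_probs = c(1, 1, 1, 1)), "sum to 1")
  one_hot <- c(0, 0, 0, 1)
  pop <- sample_population(50, class_probs = one_hot, silenced_frac = 0,
                           seed = 1)
  expect_true(all(pop$remodel_class == "no_change"))
  expect_identical(sample_population(20, seed = 3),
                   sample_population(20, seed = 3))

  pop <- sample_population(300, seed = 2)
  sil <- pop$remodel_class == "silenced"
  expect_true(all(pop$spont_anes[sil] == 0 & pop$gain_anes[sil] == 0))
  expect_true(all(pop$spont_anes <= pop$spont_wake))
  expect_true(all(pop$spont_wake >= 0 & pop$spont_wake <= 100))
  sc <- pop$remodel_class == "sign_change"
  expect_true(all(sign(pop$gain_wake[sc]) != sign(pop$gain_anes[sc])))
})

test_that("class fractions converge to the multinomial probabilities", {
  probs <- c(24, 34, 35, 36) / 129
  pop <- sample_population(10000, class_probs = probs, silenced_frac = 0,
                           seed = 4)
  frac <- table(factor(pop$remodel_class,
                       levels = soundstates:::REMODEL_CLASSES)) / 10000
  expect_true(all(abs(as.numeric(frac) - probs) < 0.02))
})

test_that("rate model gives the analytic plateau, tuning and rectification", {
  pop <- sample_population(1, silenced_frac = 0, seed = 1)
  n <- pop[1, ]
  n$bf_wake <- 10; n$hw_wake <- 0.5; n$gain_wake <- 20
  n$spont_wake <- 5; n$thr_wake <- 50
  tone_bf <- sound_stimulus("pure_tone", 0.3, 70, freqs = 10)
  r <- rate_timecourse(n, tone_bf, "wake", 0.001)
  expect_equal(max(r), 25, tolerance = 1e-3)   # spont + gain, gate ~ 1
  # half a (full) half-width away: driven component = gain / 2
  tone_off <- sound_stimulus("pure_tone", 0.3, 70, freqs = 10 * 2^0.25)
  expect_equal(max(rate_timecourse(n, tone_off, "wake", 0.001)), 15,
               tolerance = 1e-2)
  # suppression rectifies at zero
  n$gain_wake <- -10; n$spont_wake <- 5
  r <- rate_timecourse(n, tone_bf, "wake", 0.001)
  expect_true(all(r >= 0))
  expect_equal(min(r), 0, tolerance = 1e-6)
})

test_that("generate_spikes is inhomogeneous Poisson (count oracle)", {
  expect_length(generate_spikes(rep(0, 100), 0.01, seed = 1), 0)
  # rate 10 spk/s over 100 s: counts ~ Poisson(1000)
  counts <- vapply(1:100, function(s)
    length(generate_spikes(rep(10, 1000), 0.1, seed = s)), 0L)
  expect_equal(mean(counts), 1000, tolerance = 0.015)
  expect_equal(stats::var(counts), 1000, tolerance = 0.5)
  # disjoint windows are independent
  n1 <- n2 <- numeric(200)
  for (s in 1:200) {
    st <- generate_spikes(rep(20, 1000), 0.1, seed = 1000 + s)
    n1[s] <- sum(st < 50); n2[s] <- sum(st >= 50)
  }
  expect_lt(abs(stats::cor(n1, n2)), 0.2)
  expect_error(generate_spikes(c(-1, 2), 0.01), "non-negative")
})

test_that("templates: zero jitter identical, jittered pairs beat chance", {
  pop <- sample_population(60, seed = 5)
  t0 <- generate_templates(pop, jitter_sd = 0, seed = 6)
  expect_equal(t0$wake[[1]]$waveform, t0$anes[[1]]$waveform)
  expect_equal(stats::cor(as.numeric(t0$wake[[5]]$waveform),
                          as.numeric(t0$anes[[5]]$waveform)), 1)
  tj <- generate_templates(pop, jitter_sd = 0.05, seed = 6)
  corr <- template_correlation_matrix(tj$wake, tj$anes)
  true_pair <- diag(corr$rho)
  cross_rec <- corr$rho[!corr$same_recording]
  expect_gt(stats::median(true_pair), stats::quantile(cross_rec, 0.95))
  expect_error(generate_templates(pop, jitter_sd = -1), "jitter")
})

test_that("synthesized voltage matches the Gaussian-MAD and amplitude oracles", {
  pop <- sample_population(2, seed = 1)
  tm <- generate_templates(pop, seed = 2)
  # no spikes: MAD of pure Gaussian noise ~ 0.6745 sigma
  v <- synthesize_voltage(list(numeric(0)), tm$wake[1], noise_sd = 12,
                          duration_s = 0.5, seed = 3)
  expect_equal(compute_mad(as.numeric(v)), 0.6745 * 12, tolerance = 0.02)
  # single spike, zero noise: max |trace| equals the template amplitude
  v1 <- synthesize_voltage(list(0.25), tm$wake[1], noise_sd = 0,
                           duration_s = 0.5, seed = 3)
  expect_equal(max(abs(v1)), max(abs(tm$wake[[1]]$waveform)))
  # denser spiking raises the fluctuation estimate (wake vs anesthesia)
  sp_wake <- generate_spikes(rep(80, 50), 0.01, seed = 4)
  sp_anes <- generate_spikes(rep(8, 50), 0.01, seed = 5)
  vw <- synthesize_voltage(list(sp_wake), tm$wake[1], 5, 0.5, seed = 6)
  va <- synthesize_voltage(list(sp_anes), tm$wake[1], 5, 0.5, seed = 6)
  expect_gt(fluctuation_ratio(as.numeric(vw), as.numeric(va)), 1)
})

test_that("session simulation honors ground truth across states", {
  w <- small_world()
  sil <- which(w$pop$remodel_class == "silenced")
  expect_true(length(sil) > 0)
  # silenced units emit zero anesthesia spikes
  expect_true(all(vapply(w$anes$trains[sil], length, 0L) == 0))
  # sign-change units: negative wake / positive anesthesia drive at BF
  sc <- which(w$pop$remodel_class == "sign_change" &
                w$pop$gain_wake < 0)
  for (u in sc[seq_len(min(3, length(sc)))]) {
    tone <- sound_stimulus("pure_tone", 0.3, 70, freqs = w$pop$bf_wake[u])
    rw <- rate_timecourse(w$pop[u, ], tone, "wake", 0.001)
    ra <- rate_timecourse(w$pop[u, ], tone, "anesthesia", 0.001)
    expect_lt(min(rw - w$pop$spont_wake[u]), 0)
    expect_gt(max(ra - w$pop$spont_anes[u]), 0)
  }
  # determinism
  s1 <- simulate_session_spikes(w$pop[1:2, ], w$set, w$schedule, "wake",
                                seed = 11)
  s2 <- simulate_session_spikes(w$pop[1:2, ], w$set, w$schedule, "wake",
                                seed = 11)
  expect_identical(s1$trains, s2$trains)
})
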