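# Pseudo-population nearest-neighbor decoding.

# small full (binned) tensor with per-sound patterns + optional trial noise
pattern_tensor <- function(n_units, n_sounds, n_reps, n_bins = 8, noise = 0,
                           seed = 1, patterns = NULL) {
  set.seed(seed)
  if (is.null(patterns))
    patterns <- array(stats::rnorm(n_units * n_sounds * n_bins),
                      c(n_units, n_sounds, n_bins))
  v <- array(0, c(n_units, n_sounds, n_reps, n_bins))
  for (r in seq_len(n_reps))
    v[, , r, ] <- patterns + stats::rnorm(length(patterns), 0, noise)
  soundstates:::new_response_tensor(
    v, bin_s = 0.01, window = c(0, n_bins * 0.01), baseline_window = c(0, 0),
    unit_ids = seq_len(n_units), sound_ids = seq_len(n_sounds),
    durations = stats::setNames(rep(n_bins * 0.01, n_sounds),
                                seq_len(n_sounds)))
}

test_that("noiseless distinct patterns decode perfectly in both modes", {
  tens <- pattern_tensor(4, 6, 4, noise = 0)
  for (mode in c("time_course", "time_averaged")) {
    res <- nn_classify(tens, NULL, mode = mode, n_splits = 10, seed = 2)
    expect_equal(res$accuracy, 1)
    expect_true(all(diag(res$confusion) == 10))
    expect_equal(unname(category_accuracy(
      res, stats::setNames(rep(c("a", "b"), 3), 1:6))), c(1, 1))
  }
})

test_that("pure-noise responses decode at chance (1/307)", {
  tens <- pattern_tensor(20, 307, 12, noise = 10,
                         patterns = array(0, c(20, 307, 1)), n_bins = 1)
  res <- nn_classify(tens, NULL, mode = "time_averaged", n_splits = 20,
                     seed = 3)
  expect_lt(abs(res$accuracy - 1 / 307), 0.01)
  ca <- category_accuracy(res, stats::setNames(
    rep(letters[1:7], length.out = 307), 1:307))
  expect_true(all(ca < 0.05))
})

test_that("classifier matches the brute-force nearest-correlation oracle", {
  # <= 5 sounds, 2 neurons, 4 trials; noiseless so the split is irrelevant
  for (seed in 1:5) {
    tens <- pattern_tensor(2, 5, 4, n_bins = 3, noise = 0, seed = seed)
    res <- nn_classify(tens, NULL, mode = "time_course", n_splits = 4,
                       seed = seed)
    # oracle: exhaustive argmax of Pearson correlation between per-sound
    # mean vectors (train mean equals test mean without noise)
    M <- sapply(1:5, function(s) as.numeric(tens$values[, s, 1, ]))
    pred <- vapply(1:5, function(j) {
      cors <- vapply(1:5, function(i) stats::cor(M[, i], M[, j]), 0)
      which.max(cors)
    }, 0L)
    got <- apply(res$confusion, 1, which.max)
    expect_equal(unname(got), pred)
    expect_true(all(res$confusion[cbind(1:5, pred)] == 4))
  }
})

test_that("accuracy is invariant to common positive rescaling", {
  tens <- pattern_tensor(5, 8, 6, noise = 0.8, seed = 4)
  t2 <- tens; t2$values <- t2$values * 7.3
  r1 <- nn_classify(tens, NULL, mode = "time_course", n_splits = 10, seed = 5)
  r2 <- nn_classify(t2, NULL, mode = "time_course", n_splits = 10, seed = 5)
  expect_equal(r1$per_split_accuracy, r2$per_split_accuracy)
  expect_equal(r1$confusion, r2$confusion)
})

test_that("added trial noise monotonically degrades expected accuracy", {
  accs <- vapply(c(0, 1.5, 8), function(ns) {
    mean(vapply(1:3, function(s)
      nn_classify(pattern_tensor(6, 12, 6, noise = ns, seed = 10 + s),
                  NULL, mode = "time_course", n_splits = 10,
                  seed = s)$accuracy, 0))
  }, 0)
  expect_equal(accs[1], 1)
  expect_true(accs[2] > accs[3])
  expect_true(accs[1] >= accs[2])
})

test_that("pseudo-population pooling concatenates units and permutes trials", {
  t1 <- pattern_tensor(3, 6, 5, noise = 1, seed = 6)
  t2 <- pattern_tensor(4, 6, 5, noise = 1, seed = 7)
  pool <- assemble_pseudopopulation(list(t1, t2), seed = 8)
  expect_equal(dim(pool$values)[1], 7)
  # single recording: identity up to a per-sound trial permutation
  p1 <- assemble_pseudopopulation(list(t1), seed = 9)
  for (s in 1:6)
    expect_equal(sort(p1$values[1, s, , 1]), sort(t1$values[1, s, , 1]))
  bad <- pattern_tensor(3, 7, 5)
  expect_error(assemble_pseudopopulation(list(t1, bad)), "mismatched")
})

test_that("cross-state design: identity equals same-state, permutation kills it", {
  tens <- pattern_tensor(12, 20, 6, noise = 0.5, seed = 10)
  same <- nn_classify(tens, NULL, mode = "time_course", n_splits = 10,
                      seed = 11)
  crossed <- cross_state_design(tens, tens, mode = "time_course",
                                n_splits = 10, seed = 11)
  expect_equal(crossed$wake_to_anes$accuracy, same$accuracy)
  expect_equal(crossed$accuracy, same$accuracy)
  # neuron-permuted second state destroys the correspondence
  perm <- subset_tensor(tens, c(7:12, 1:6))
  perm$unit_ids <- tens$unit_ids
  got <- cross_state_design(tens, perm, mode = "time_course", n_splits = 10,
                            seed = 11)
  expect_gt(same$accuracy, 0.9)
  expect_lt(got$accuracy, 0.2)
  expect_error(cross_state_design(tens, subset_tensor(tens, 1:3)),
               "unit")
})

test_that("category bootstrap: null difference centered at 0, degenerate n_boot", {
  tens <- pattern_tensor(10, 12, 6, noise = 1, seed = 12)
  cmap <- stats::setNames(rep(c("x", "y", "z"), 4), 1:12)
  bt <- bootstrap_category_difference(tens, tens, cmap, n_boot = 20,
                                      n_splits = 5, seed = 13)
  expect_equal(dim(bt$differences), c(20, 3))
  expect_true(all(abs(bt$mean) < 0.2))
  expect_true(all(bt$p_value >= 0.05))
  expect_warning(
    b1 <- bootstrap_category_difference(tens, tens, cmap, n_boot = 1,
                                        n_splits = 5, seed = 14),
    "unstable")
  expect_true(all(b1$p_value %in% c(0, 0.5, 1)))
})

test_that("a real cross-state degradation is detected by the bootstrap", {
  # anesthesia responses for category "x" carry no signal
  set.seed(15)
  pat <- array(stats::rnorm(10 * 12 * 1), c(10, 12, 1))
  tw <- pattern_tensor(10, 12, 6, noise = 0.6, patterns = pat, n_bins = 1)
  pat_a <- pat; pat_a[, 1:6, ] <- 0
  ta <- pattern_tensor(10, 12, 6, noise = 0.6, patterns = pat_a, n_bins = 1,
                       seed = 16)
  cmap <- stats::setNames(rep(c("x", "y"), each = 6), 1:12)
  bt <- bootstrap_category_difference(tw, ta, cmap, n_boot = 30,
                                      n_splits = 10, seed = 17)
  expect_gt(bt$mean["x"], 0.2)
  expect_lt(bt$p_value["x"], 0.05)
})
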