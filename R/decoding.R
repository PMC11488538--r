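## Pseudo-population nearest-neighbor sound decoding.
##
## For each of `n_splits` random half-splits of trials, per-sound train
## vectors are trial means over one half and test vectors over the other
## half; a test sound is assigned to the train sound with the most correlated
## population vector (Pearson). Same-state and cross-state designs share the
## split machinery.

# features per trial: [reps, sounds, features]; time_course concatenates
# post-onset bins of all units, time_averaged uses per-unit mean rates
decode_features <- function(tensor, mode) {
  mode <- match.arg(mode, c("time_course", "time_averaged"))
  d <- dim(tensor$values)
  if (mode == "time_averaged" || tensor$rate_only) {
    rates <- response_rates(tensor)          # [u, s, r]
    aperm(rates, c(3, 2, 1))
  } else {
    centers <- seq(tensor$window[1] + tensor$bin_s / 2, tensor$window[2],
                   by = tensor$bin_s)
    post <- which(centers > 0)
    v <- tensor$values[, , , post, drop = FALSE]  # [u, s, r, b]
    v <- aperm(v, c(3, 2, 1, 4))                  # [r, s, u, b]
    dim(v) <- c(d[3], d[2], d[1] * length(post))
    v
  }
}

# mean feature matrix [sounds x features] over a set of trials
split_mean <- function(feat, reps) {
  m <- colMeans(feat[reps, , , drop = FALSE])
  matrix(m, nrow = dim(feat)[2])
}

#' Assemble a pseudo-population from several recordings
#'
#' Concatenates neurons from per-recording response tensors after
#' independently permuting trial order within each recording (and each
#' sound), emulating the random trial pairing of a pseudo-population.
#'
#' @param tensors List of `response_tensor`s with identical sound sets, trial
#'   counts and bin structure.
#' @param seed Integer seed for the trial permutations.
#' @return A pooled `response_tensor`.
#' @export
assemble_pseudopopulation <- function(tensors, seed = 0L) {
  stopifnot(length(tensors) >= 1)
  ref <- tensors[[1]]
  for (tn in tensors[-1]) {
    if (!identical(tn$sound_ids, ref$sound_ids) ||
        !identical(dim(tn$values)[2:4], dim(ref$values)[2:4]))
      stop_invalid("tensors have mismatched sound sets or dimensions")
  }
  local_seed(seed, {
    perm_vals <- lapply(tensors, function(tn) {
      v <- tn$values
      d <- dim(v)
      for (s in seq_len(d[2]))
        v[, s, , ] <- v[, s, sample(d[3]), , drop = FALSE]
      v
    })
    d2 <- dim(ref$values); d2[1] <- sum(vapply(perm_vals, function(v) dim(v)[1], 0L))
    out <- array(0, d2)
    at <- 0L
    for (v in perm_vals) {
      out[at + seq_len(dim(v)[1]), , , ] <- v
      at <- at + dim(v)[1]
    }
    new_response_tensor(out, ref$bin_s, ref$window, ref$baseline_window,
                        unit_ids = seq_len(d2[1]), sound_ids = ref$sound_ids,
                        durations = ref$durations, rate_only = ref$rate_only)
  })
}

#' Subset a response tensor by unit index
#'
#' @param tensor A `response_tensor`.
#' @param unit_idx Integer indices (repeats allowed, e.g. bootstrap draws).
#' @return A `response_tensor` over the selected units.
#' @export
subset_tensor <- function(tensor, unit_idx) {
  new_response_tensor(tensor$values[unit_idx, , , , drop = FALSE],
                      tensor$bin_s, tensor$window, tensor$baseline_window,
                      unit_ids = tensor$unit_ids[unit_idx],
                      sound_ids = tensor$sound_ids,
                      durations = tensor$durations,
                      rate_only = tensor$rate_only,
                      baseline = if (!is.null(tensor$baseline))
                        tensor$baseline[unit_idx, , , drop = FALSE])
}

# core split loop shared by same-state and cross-state designs
nn_decode <- function(train_feat, test_feat, n_splits, seed, design, mode,
                      sound_ids) {
  n_reps <- dim(train_feat)[1]
  n_sounds <- dim(train_feat)[2]
  if (n_reps < 2) stop_invalid("need >= 2 trials per sound")
  n_train <- ceiling(n_reps / 2)   # odd counts: extra trial in training
  local_seed(seed, {
    acc <- numeric(n_splits)
    correct <- integer(n_sounds)
    confusion <- matrix(0L, n_sounds, n_sounds,
                        dimnames = list(sound_ids, sound_ids))
    for (k in seq_len(n_splits)) {
      tr <- sample(n_reps, n_train)
      te <- setdiff(seq_len(n_reps), tr)
      M_tr <- split_mean(train_feat, tr)
      M_te <- split_mean(test_feat, te)
      C <- suppressWarnings(stats::cor(t(M_tr), t(M_te)))
      C[is.na(C)] <- -Inf                     # zero-variance guard
      pred <- max.col(t(C), ties.method = "first")
      acc[k] <- mean(pred == seq_len(n_sounds))
      correct <- correct + (pred == seq_len(n_sounds))
      confusion[cbind(seq_len(n_sounds), pred)] <-
        confusion[cbind(seq_len(n_sounds), pred)] + 1L
    }
    per_sound <- correct / n_splits
    structure(list(per_split_accuracy = acc,
                   accuracy = mean(acc),
                   per_sound_accuracy = per_sound,
                   sem = stats::sd(per_sound) / sqrt(n_sounds),
                   confusion = confusion, mode = mode, design = design,
                   n_splits = n_splits, sound_ids = sound_ids),
              class = "decoding_result")
  })
}

#' Nearest-neighbor sound classification (same-state)
#'
#' @param train_tensor `response_tensor` providing training trials.
#' @param test_tensor `response_tensor` providing testing trials; defaults to
#'   `train_tensor` (same-state design: the two trial halves are disjoint).
#' @param mode `"time_course"` (concatenated post-onset 10-ms bins of all
#'   units) or `"time_averaged"` (per-unit mean rate over the sound).
#' @param n_splits Number of random train/test trial splits (default 50).
#' @param seed Integer seed.
#' @return A `decoding_result`: per-split accuracies, mean accuracy, SEM over
#'   sounds, per-sound accuracies and the sounds-by-sounds confusion matrix
#'   (rows = presented sound, entries sum to `n_splits` per row).
#' @export
nn_classify <- function(train_tensor, test_tensor = NULL,
                        mode = c("time_course", "time_averaged"),
                        n_splits = 50, seed = 0L) {
  mode <- match.arg(mode)
  same <- is.null(test_tensor)
  if (same) test_tensor <- train_tensor
  if (!identical(train_tensor$sound_ids, test_tensor$sound_ids))
    stop_invalid("train and test tensors cover different sounds")
  if (dim(train_tensor$values)[3] != dim(test_tensor$values)[3])
    stop_invalid("train and test tensors have different trial counts")
  nn_decode(decode_features(train_tensor, mode),
            decode_features(test_tensor, mode),
            n_splits, seed, design = if (same) "same_state" else "cross_state",
            mode = mode, sound_ids = train_tensor$sound_ids)
}

#' Cross-state decoding in both directions
#'
#' Trains on trial halves from one state and tests on the complementary trial
#' halves of the other state, for both directions; unit identities must be
#' aligned across the two tensors.
#'
#' @param wake_tensor,anes_tensor Neuron-aligned `response_tensor`s.
#' @inheritParams nn_classify
#' @return List of class `cross_state_result` with `wake_to_anes`,
#'   `anes_to_wake` (both `decoding_result`s) and `accuracy` (their mean).
#' @export
cross_state_design <- function(wake_tensor, anes_tensor,
                               mode = c("time_course", "time_averaged"),
                               n_splits = 50, seed = 0L) {
  mode <- match.arg(mode)
  if (!identical(wake_tensor$unit_ids, anes_tensor$unit_ids))
    stop_invalid("unit identities differ between states")
  wa <- nn_classify(wake_tensor, anes_tensor, mode, n_splits, seed)
  aw <- nn_classify(anes_tensor, wake_tensor, mode, n_splits, seed)
  wa$design <- aw$design <- "cross_state"
  structure(list(wake_to_anes = wa, anes_to_wake = aw,
                 accuracy = mean(c(wa$accuracy, aw$accuracy))),
            class = "cross_state_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result (%s, %s): accuracy %.3f +/- %.3f (SEM over %d sounds, %d splits)\n",
              x$design, x$mode, x$accuracy, x$sem, length(x$sound_ids),
              x$n_splits))
  invisible(x)
}

#' Map each sound of a battery to a decoding category
#'
#' @param set A `stimulus_set`.
#' @param split_tone_levels If `TRUE` (default), pure tones are split into
#'   `pure_tone_50` and `pure_tone_70` (14 sounds each), matching how
#'   category-level accuracies are usually reported.
#' @return Named character vector, names = sound ids.
#' @export
sound_category_map <- function(set, split_tone_levels = TRUE) {
  tab <- set$table
  cat <- tab$category
  if (split_tone_levels) {
    pt <- cat == "pure_tone"
    cat[pt] <- paste0("pure_tone_", tab$level_db[pt])
  }
  stats::setNames(cat, tab$sound_id)
}

#' Per-category decoding accuracy
#'
#' Restricts the per-sound accuracies of a full-battery decoding run to each
#' sound category (the prediction itself remains 307-way).
#'
#' @param result A `decoding_result`.
#' @param category_map Named vector mapping sound id to category (see
#'   [sound_category_map()]).
#' @return Named numeric vector of accuracies per category.
#' @export
category_accuracy <- function(result, category_map) {
  cats <- category_map[as.character(result$sound_ids)]
  if (anyNA(cats)) stop_invalid("category_map does not cover all sounds")
  vapply(split(result$per_sound_accuracy, cats), mean, 0)
}

#' Neuron-level bootstrap of cross-state category-accuracy differences
#'
#' For each of `n_boot` bootstrap populations (units resampled with
#' replacement, independently per state), computes same-state decoding
#' accuracy per category in each state and their wake-minus-anesthesia
#' difference. The one-sided p-value per category is the fraction of
#' bootstrap differences on the opposite side of 0 from the mean.
#'
#' @param wake_tensor,anes_tensor `response_tensor`s (need not be
#'   neuron-aligned; resampling is per state).
#' @param category_map Named vector mapping sound id to category.
#' @param n_boot Number of bootstrap resamples (default 100; < 10 warns).
#' @param n_splits Train/test splits per resample (default 50).
#' @param mode Decoding mode.
#' @param seed Integer seed.
#' @return List with `differences` (n_boot x categories matrix), `mean`,
#'   `p_value` (per category) and parameters.
#' @export
bootstrap_category_difference <- function(wake_tensor, anes_tensor,
                                          category_map, n_boot = 100,
                                          n_splits = 50,
                                          mode = "time_averaged",
                                          seed = 0L) {
  if (n_boot < 10)
    warning("n_boot < 10: bootstrap p-values will be unstable")
  n_w <- dim(wake_tensor$values)[1]
  n_a <- dim(anes_tensor$values)[1]
  draws <- local_seed(seed, list(
    w = replicate(n_boot, sample(n_w, replace = TRUE), simplify = FALSE),
    a = replicate(n_boot, sample(n_a, replace = TRUE), simplify = FALSE)))
  diffs <- NULL
  for (b in seq_len(n_boot)) {
    rw <- nn_classify(subset_tensor(wake_tensor, draws$w[[b]]), NULL,
                      mode = mode, n_splits = n_splits, seed = seed + b)
    ra <- nn_classify(subset_tensor(anes_tensor, draws$a[[b]]), NULL,
                      mode = mode, n_splits = n_splits, seed = seed + b)
    d <- category_accuracy(rw, category_map) -
      category_accuracy(ra, category_map)
    diffs <- rbind(diffs, d)
  }
  rownames(diffs) <- NULL
  m <- colMeans(diffs)
  p <- vapply(seq_along(m), function(j) {
    if (m[j] == 0) return(0.5)
    mean(diffs[, j] * sign(m[j]) < 0)
  }, 0)
  names(p) <- names(m)
  list(differences = diffs, mean = m, p_value = p,
       n_boot = n_boot, n_splits = n_splits, mode = mode,
       seed = as.integer(seed))
}
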