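## Cross-state unit matching by template correlation against an empirical
## chance null built from cross-recording template pairs.

# flatten a template to a vector, cropped to `n_ch` channels centred on its
# peak channel (the channel extent actually compared is configurable)
flatten_template <- function(tmpl, n_ch = NULL) {
  w <- tmpl$waveform
  if (!is.null(n_ch) && n_ch < nrow(w)) {
    half <- n_ch %/% 2
    lo <- min(max(1, tmpl$peak_channel - half), nrow(w) - n_ch + 1)
    w <- w[lo:(lo + n_ch - 1), , drop = FALSE]
  }
  as.numeric(w)
}

#' Template correlation matrix between two states
#'
#' Pearson correlation of flattened waveforms for every wake-by-anesthesia
#' template pair, plus a logical mask marking pairs recorded simultaneously
#' (same recording). Cross-recording pairs are kept at their true correlation
#' value; the mask, not overwriting, encodes which pairs are eligible matches
#' and which feed the chance null.
#'
#' @param wake,anes Lists of templates (`unit_id`, `recording_id`,
#'   `waveform`, `peak_channel`).
#' @param n_channels_window Number of channels (centred on each template's
#'   peak channel) used for the comparison; `NULL` uses all channels.
#' @return List with `rho` (wake x anes correlation matrix, dimnames = unit
#'   ids) and `same_recording` (logical matrix).
#' @export
template_correlation_matrix <- function(wake, anes, n_channels_window = NULL) {
  geom <- function(tl) vapply(tl, function(t) dim(t$waveform), c(0, 0))
  gw <- geom(wake); ga <- geom(anes)
  if (length(unique(c(gw[1, ], ga[1, ]))) > 1 ||
      length(unique(c(gw[2, ], ga[2, ]))) > 1)
    stop_invalid("templates do not share channel/sample geometry")
  W <- sapply(wake, flatten_template, n_ch = n_channels_window)
  A <- sapply(anes, flatten_template, n_ch = n_channels_window)
  rho <- stats::cor(W, A)
  rw <- vapply(wake, `[[`, 0, "recording_id")
  ra <- vapply(anes, `[[`, 0, "recording_id")
  dimnames(rho) <- list(vapply(wake, `[[`, 0, "unit_id"),
                        vapply(anes, `[[`, 0, "unit_id"))
  list(rho = rho, same_recording = outer(rw, ra, "=="))
}

#' Chance correlation threshold from cross-recording pairs
#'
#' For each wake template, takes its maximal correlation over anesthesia
#' templates from *other* recordings (which cannot be the same neuron); the
#' threshold is the stated percentile of this empirical null of
#' maximally correlated chance pairs.
#'
#' @param corr Output of [template_correlation_matrix()].
#' @param percentile Percentile of the null distribution (default 95, i.e.
#'   chance similarity probability below 0.05).
#' @return The correlation threshold, with the null maxima attached as
#'   attribute `"null_distribution"`.
#' @export
chance_threshold <- function(corr, percentile = 95) {
  cross <- corr$rho
  cross[corr$same_recording] <- NA
  if (all(is.na(cross)))
    stop_invalid("cannot build chance null: need templates from >= 2 recordings")
  null_max <- apply(cross, 1, function(x) if (all(is.na(x))) NA
                    else max(x, na.rm = TRUE))
  null_max <- null_max[!is.na(null_max)]
  structure(as.numeric(stats::quantile(null_max, percentile / 100)),
            null_distribution = as.numeric(null_max))
}

#' Match units across states
#'
#' For each wake unit, the best-correlated simultaneously recorded anesthesia
#' template (rho_max) is a candidate match; it is accepted iff
#' `rho_max > threshold` and every other simultaneously recorded anesthesia
#' unit correlates below `rho_max - margin` (ambiguity rejection). A final
#' mutual-best filter enforces one-to-one pairing (an anesthesia unit claimed
#' by several wake units keeps only its best partner).
#'
#' @param corr Output of [template_correlation_matrix()].
#' @param threshold Correlation acceptance threshold (e.g. from
#'   [chance_threshold()]).
#' @param margin Ambiguity margin (default 0.2).
#' @return Object of class `match_result`: list with `pairs` (data.frame
#'   `wake_unit`, `anes_unit`, `rho_max`), `rejected` (data.frame with
#'   `reason` in below_threshold/ambiguous/duplicate), `threshold`, `margin`.
#' @export
match_units <- function(corr, threshold, margin = 0.2) {
  rho <- corr$rho; same <- corr$same_recording
  wake_ids <- as.numeric(rownames(rho)); anes_ids <- as.numeric(colnames(rho))
  pairs <- list(); rejected <- list()
  for (i in seq_len(nrow(rho))) {
    cand <- which(same[i, ])
    if (!length(cand)) next
    r <- rho[i, cand]
    j <- cand[which.max(r)]
    rho_max <- max(r)
    competitors <- r[cand != j]
    if (rho_max <= threshold) {
      rejected[[length(rejected) + 1]] <-
        data.frame(wake_unit = wake_ids[i], anes_unit = anes_ids[j],
                   rho_max = rho_max, reason = "below_threshold")
    } else if (length(competitors) && any(competitors >= rho_max - margin)) {
      rejected[[length(rejected) + 1]] <-
        data.frame(wake_unit = wake_ids[i], anes_unit = anes_ids[j],
                   rho_max = rho_max, reason = "ambiguous")
    } else {
      pairs[[length(pairs) + 1]] <-
        data.frame(wake_unit = wake_ids[i], anes_unit = anes_ids[j],
                   rho_max = rho_max)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(wake_unit = numeric(), anes_unit = numeric(),
               rho_max = numeric())
  # mutual-best one-to-one enforcement
  if (nrow(pairs) > 1 && anyDuplicated(pairs$anes_unit)) {
    keep <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$anes_unit),
                          function(ix) ix[which.max(pairs$rho_max[ix])]))
    dup <- setdiff(seq_len(nrow(pairs)), keep)
    if (length(dup))
      rejected[[length(rejected) + 1]] <-
        data.frame(wake_unit = pairs$wake_unit[dup],
                   anes_unit = pairs$anes_unit[dup],
                   rho_max = pairs$rho_max[dup], reason = "duplicate")
    pairs <- pairs[sort(keep), , drop = FALSE]
  }
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(wake_unit = numeric(), anes_unit = numeric(),
               rho_max = numeric(), reason = character())
  structure(list(pairs = pairs, rejected = rejected,
                 threshold = threshold, margin = margin),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d accepted pair(s), %d rejected (threshold %.3f, margin %.2f)\n",
              nrow(x$pairs), nrow(x$rejected), x$threshold, x$margin))
  invisible(x)
}

#' Precision and recall of a match result against ground truth
#'
#' On simulated data the true correspondence is `wake_unit == anes_unit`.
#'
#' @param result A `match_result`.
#' @param true_pairs Data frame with columns `wake_unit`, `anes_unit`; by
#'   default the identity pairing over the wake units present in `result`.
#' @return Named vector with `precision`, `recall`, `n_accepted`.
#' @export
match_performance <- function(result, true_pairs = NULL) {
  p <- result$pairs
  correct <- if (is.null(true_pairs)) p$wake_unit == p$anes_unit else
    mapply(function(w, a) any(true_pairs$wake_unit == w &
                                true_pairs$anes_unit == a),
           p$wake_unit, p$anes_unit)
  n_true <- if (is.null(true_pairs))
    length(unique(c(p$wake_unit, result$rejected$wake_unit))) else
    nrow(true_pairs)
  c(precision = if (nrow(p)) mean(correct) else NA_real_,
    recall = if (n_true) sum(correct) / n_true else NA_real_,
    n_accepted = nrow(p))
}
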