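## State-subspace analysis: PCA projection of per-(sound, state) population
## vectors, cross-validated linear maximum-margin state classification, and
## the rotation-to-boundary regression.
##
## The linear SVM is solved internally by dual coordinate descent
## (L2-regularized hinge loss); no external solver is required.

#' Per-(sound, state) population vectors
#'
#' One vector per sound and state: the mean response of every neuron over
#' trials and time bins during sound presentation.
#'
#' @param wake_tensor,anes_tensor Neuron-aligned `response_tensor`s.
#' @return List with `vectors` (2 x n_sounds rows by n_neurons columns; wake
#'   rows first), `state` (label per row) and `sound_id`.
#' @export
sound_state_vectors <- function(wake_tensor, anes_tensor) {
  if (!identical(wake_tensor$unit_ids, anes_tensor$unit_ids))
    stop_invalid("unit identities differ between states")
  if (!identical(wake_tensor$sound_ids, anes_tensor$sound_ids))
    stop_invalid("sound sets differ between states")
  mw <- t(apply(response_rates(wake_tensor), c(1, 2), mean))  # sounds x units
  ma <- t(apply(response_rates(anes_tensor), c(1, 2), mean))
  list(vectors = rbind(mw, ma),
       state = rep(c("wake", "anesthesia"), each = nrow(mw)),
       sound_id = rep(wake_tensor$sound_ids, 2))
}

#' Project vectors onto principal components
#'
#' Components are computed from the covariance of all samples jointly (both
#' states pooled), mean-centred and unscaled.
#'
#' @param vectors Samples x features matrix (e.g. `sound_state_vectors()`
#'   output) or the full list returned by that function.
#' @param k Number of components to retain (default 3); reduced with a
#'   warning if it exceeds the rank.
#' @return List of class `state_space_projection`: `projections` (samples x
#'   k scores), `explained_variance` (fraction per retained component,
#'   non-increasing), `rotation`, `center`, plus `state`/`sound_id` if the
#'   input carried them.
#' @export
pca_project <- function(vectors, k = 3) {
  meta <- NULL
  if (is.list(vectors) && !is.null(vectors$vectors)) {
    meta <- vectors[c("state", "sound_id")]
    vectors <- vectors$vectors
  }
  if (nrow(vectors) < k)
    stop_invalid("need at least k = %d samples", k)
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; reduced", k, rank))
    k <- rank
  }
  out <- list(projections = pc$x[, seq_len(k), drop = FALSE],
              explained_variance = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
              rotation = pc$rotation[, seq_len(k), drop = FALSE],
              center = pc$center)
  structure(c(out, meta), class = "state_space_projection")
}

# Linear L1-loss SVM via dual coordinate descent on standardized features.
# Returns the boundary (w, b) in the original feature space: w.x + b = 0.
linear_svm_fit <- function(X, y, C = 1, max_epochs = 200, tol = 1e-6) {
  stopifnot(all(y %in% c(-1, 1)))
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- cbind(sweep(sweep(X, 2, mu), 2, sdev, "/"), bias = 1)
  n <- nrow(Xs); p <- ncol(Xs)
  Q <- rowSums(Xs^2)
  alpha <- numeric(n)
  w <- numeric(p)
  for (ep in seq_len(max_epochs)) {
    delta <- 0
    for (i in seq_len(n)) {
      G <- y[i] * sum(w * Xs[i, ]) - 1
      a_new <- min(max(alpha[i] - G / Q[i], 0), C)
      d <- a_new - alpha[i]
      if (abs(d) > 1e-14) {
        w <- w + d * y[i] * Xs[i, ]
        alpha[i] <- a_new
        delta <- max(delta, abs(d))
      }
    }
    if (delta < tol) break
  }
  w_orig <- w[seq_len(p - 1)] / sdev
  b_orig <- w[p] - sum(w[seq_len(p - 1)] * mu / sdev)
  list(w = w_orig, b = b_orig)
}

svm_predict <- function(fit, X) {
  ifelse(as.numeric(X %*% fit$w) + fit$b >= 0, 1, -1)
}

#' Cross-validated linear state classification in PC space
#'
#' Fits a linear maximum-margin classifier (hinge loss, `C = 1`) to separate
#' the two states in the projected space and reports mean held-out accuracy
#' over `n_folds` folds. Folds partition *sounds*: each fold contains both
#' states' samples of its sounds, preserving a 1-to-1 state ratio per fold.
#'
#' @param projection A `state_space_projection` (with `state` labels), or a
#'   samples x k matrix together with `state_labels`.
#' @param state_labels Character/factor labels per row (two levels); taken
#'   from `projection$state` when omitted.
#' @param sound_ids Sound identity per row, used to build sound-stratified
#'   folds; taken from `projection$sound_id` when available, otherwise folds
#'   stratify by state.
#' @param n_folds Number of cross-validation folds (default 10).
#' @param C Soft-margin cost (default 1).
#' @param seed Integer seed for fold assignment.
#' @return List with `cv_accuracy`, `fold_accuracy`, and `boundary`
#'   (`w`, `b` of the full-data decision plane `w.x + b = 0`).
#' @export
svm_state_classification <- function(projection, state_labels = NULL,
                                     sound_ids = NULL, n_folds = 10, C = 1,
                                     seed = 0L) {
  X <- if (inherits(projection, "state_space_projection"))
    projection$projections else as.matrix(projection)
  if (is.null(state_labels) && !is.null(projection$state))
    state_labels <- projection$state
  if (is.null(sound_ids) && !is.null(projection$sound_id))
    sound_ids <- projection$sound_id
  lv <- unique(state_labels)
  if (length(lv) != 2) stop_invalid("need exactly two state labels")
  y <- ifelse(state_labels == lv[1], 1, -1)
  folds <- local_seed(seed, {
    if (!is.null(sound_ids)) {
      us <- unique(sound_ids)
      fs <- sample(rep(seq_len(n_folds), length.out = length(us)))
      fs[match(sound_ids, us)]
    } else {
      unlist(lapply(split(seq_along(y), y), function(ix)
        stats::setNames(sample(rep(seq_len(n_folds), length.out = length(ix))),
                        ix)))[as.character(seq_along(y))]
    }
  })
  fold_acc <- vapply(seq_len(n_folds), function(f) {
    te <- which(folds == f)
    if (!length(te)) return(NA_real_)
    fit <- linear_svm_fit(X[-te, , drop = FALSE], y[-te], C = C)
    mean(svm_predict(fit, X[te, , drop = FALSE]) == y[te])
  }, 0)
  full <- linear_svm_fit(X, y, C = C)
  list(cv_accuracy = mean(fold_acc, na.rm = TRUE),
       fold_accuracy = fold_acc,
       boundary = full, levels = lv)
}

#' Rotate 2-PC projections to the decision boundary
#'
#' Rotates the first-two-PC plane so that one axis is normal to the linear
#' decision line and the other collinear with it, then correlates wake and
#' anesthesia coordinates of each sound on both axes (Pearson). A pure
#' cross-state shift along the normal axis leaves the collinear coordinates
#' perfectly correlated.
#'
#' @param projections_2pc Samples x 2 matrix of PC1/PC2 scores.
#' @param boundary List with `w` (length-2 normal vector of the decision
#'   line); e.g. the first two components of the SVM boundary.
#' @param state,sound_id Row labels pairing wake and anesthesia samples.
#' @return List with `rotated` (samples x 2: normal and collinear
#'   coordinates), `r_normal`, `r_collinear` (per-axis Pearson r across
#'   sounds) and `angle_rad`.
#' @export
rotate_to_boundary <- function(projections_2pc, boundary, state, sound_id) {
  w <- boundary$w[1:2]
  nw <- sqrt(sum(w^2))
  if (nw == 0 || !all(is.finite(w)))
    stop_invalid("degenerate boundary direction")
  n_ax <- w / nw
  c_ax <- c(-n_ax[2], n_ax[1])
  R <- cbind(normal = n_ax, collinear = c_ax)
  rotated <- as.matrix(projections_2pc) %*% R
  states <- unique(state)
  i1 <- state == states[1]; i2 <- state == states[2]
  m <- match(sound_id[i1], sound_id[i2])
  r_n <- stats::cor(rotated[i1, 1], rotated[which(i2)[m], 1])
  r_c <- stats::cor(rotated[i1, 2], rotated[which(i2)[m], 2])
  list(rotated = rotated, r_normal = r_n, r_collinear = r_c,
       angle_rad = atan2(n_ax[1], n_ax[2]))
}
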