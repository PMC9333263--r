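#' Build decoding feature matrices
#'
#' Features are mean HGA in 100-ms windows sliding by 50 ms; window centers
#' span `-50..1500` ms for VL and `-50..2450` ms for NatS. Rows are stimuli
#' (stimulus responses) or single trials; columns are ordered channel-major,
#' window-minor (all windows of channel 1, then channel 2, ...). Windows are
#' half-open `[center - 50, center + 50)` and use whichever HGA samples fall
#' inside the clipped series (at least one sample is required).
#'
#' @param x a `vg_stim_response` or (for single-trial decoding) a `vg_hga`.
#' @param stimuli stimulus table supplying vocal labels.
#' @param cfg a [voice_config()].
#' @param channels optional character vector restricting to a channel subset
#'   (e.g. the auditory-responsive channels); default all.
#' @param windows `"all"` or a numeric vector of window centers (ms).
#' @return Object of class `vg_features`: list with matrix `X`, logical
#'   `labels`, `centers_ms`, `channel_ids`, and `task`.
#' @export
build_features <- function(x, stimuli, cfg = voice_config(), channels = NULL,
                           windows = "all") {
  single_trial <- inherits(x, "vg_hga")
  if (!single_trial && !inherits(x, "vg_stim_response")) {
    stop("x must be a vg_stim_response or vg_hga")
  }
  ch_ids <- x$channels$channel_id
  if (is.null(channels)) channels <- ch_ids
  ch_idx <- match(channels, ch_ids)
  if (anyNA(ch_idx)) stop("unknown channel id(s)")
  if (!length(ch_idx)) stop("empty channel set")
  rng <- task_center_range_ms(cfg, x$task)
  centers <- seq(rng[1], rng[2], by = cfg$window_step_ms)
  if (!identical(windows, "all")) {
    if (!all(windows %in% centers)) stop("requested windows outside the grid")
    centers <- as.numeric(windows)
  }
  half <- cfg$window_width_ms / 2
  win_idx <- lapply(centers, function(cc) {
    which(x$time_ms >= cc - half & x$time_ms < cc + half)
  })
  if (any(lengths(win_idx) == 0)) stop("window(s) with no HGA samples")
  n_row <- dim(x$data)[1]
  X <- matrix(0, nrow = n_row, ncol = length(ch_idx) * length(centers))
  col <- 0
  cn <- character(ncol(X))
  for (ci in ch_idx) {
    for (w in seq_along(centers)) {
      col <- col + 1
      X[, col] <- rowMeans(x$data[, ci, win_idx[[w]], drop = FALSE], dims = 1)
      cn[col] <- paste0(ch_ids[ci], "@", centers[w])
    }
  }
  colnames(X) <- cn
  ids <- if (single_trial) x$trials$stimulus_id else x$stimuli$stimulus_id
  labels <- stimuli$vocal[match(ids, stimuli$stimulus_id)]
  if (anyNA(labels)) stop("rows reference stimuli missing from the table")
  structure(
    list(
      X = X, labels = labels, centers_ms = centers,
      channel_ids = ch_ids[ch_idx], task = x$task,
      single_trial = single_trial
    ),
    class = "vg_features"
  )
}

# Stratified fold assignment: each class spread evenly over folds.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Inverse-class-prevalence observation weights from a training label set.
prevalence_weights <- function(labels) {
  n <- length(labels)
  w <- ifelse(labels, n / sum(labels), n / sum(!labels))
  w / mean(w)
}

# Z-score columns by training statistics; constant columns pass unscaled.
train_zscore <- function(X_train, X_other = NULL) {
  m <- colMeans(X_train)
  s <- apply(X_train, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  z <- function(X) sweep(sweep(X, 2, m), 2, s, "/")
  list(train = z(X_train), other = if (is.null(X_other)) NULL else z(X_other))
}

# glmnet needs >= 2 predictors; pad a 1-column matrix with an all-zero
# column whose coefficient is always 0.
pad_single_col <- function(X) {
  if (ncol(X) >= 2) X else cbind(X, `.pad` = 0)
}

# Fit the L1 path on train data, select lambda by inner stratified CV
# minimizing weighted binomial deviance; returns the fitted glmnet and the
# selected lambda. The path top is the analytic lambda_max of the weighted
# problem: max_j |<x_j, w (y - p0)>| / n with p0 the weighted intercept-only
# prediction (0.5 under inverse-prevalence weights), the smallest value
# zeroing all coefficients.
select_l1_model <- function(X, y, cfg) {
  w <- prevalence_weights(y)
  Xp <- pad_single_col(X)
  n <- length(y)
  p0 <- sum(w * y) / sum(w)
  lam0 <- max(abs(crossprod(Xp, w * (y - p0)))) / n
  if (lam0 <= 0) lam0 <- 1e-3
  grid <- exp(seq(log(lam0), log(lam0 * cfg$lambda_min_ratio),
    length.out = cfg$n_lambda
  ))
  foldid <- stratified_folds(y, min(cfg$n_inner_folds, min(table(y))))
  cvfit <- suppressWarnings(glmnet::cv.glmnet(Xp, factor(y),
    family = "binomial", alpha = 1,
    weights = w, lambda = grid, foldid = foldid,
    type.measure = "deviance", standardize = FALSE
  ))
  list(fit = cvfit, lambda = cvfit$lambda.min)
}

balanced_accuracy_confusion <- function(conf) {
  # conf: 2x2 matrix [truth (FALSE,TRUE) x predicted (FALSE,TRUE)]
  tnr <- if (sum(conf[1, ]) > 0) conf[1, 1] / sum(conf[1, ]) else NA
  tpr <- if (sum(conf[2, ]) > 0) conf[2, 2] / sum(conf[2, ]) else NA
  mean(c(tpr, tnr))
}

#' Balanced accuracy from predictions
#'
#' Mean of the class-conditional accuracies; chance is 0.5 regardless of
#' class imbalance.
#'
#' @param truth,predicted logical vectors.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  conf <- table(
    factor(truth, levels = c(FALSE, TRUE)),
    factor(predicted, levels = c(FALSE, TRUE))
  )
  balanced_accuracy_confusion(unclass(conf))
}

#' L1-regularized logistic decoding with nested cross-validation
#'
#' Outer 5-fold cross-validation, stratified by class. Within each outer
#' fold, features are z-scored with training+validation statistics,
#' observations weighted by inverse class prevalence (computed on
#' training+validation data), and the regularization strength is chosen from
#' a 20-value log-spaced path by 10-fold inner cross-validation minimizing
#' mean weighted binomial deviance. Balanced accuracy is computed from the
#' confusion counts pooled over outer folds.
#'
#' @param X feature matrix (rows = stimuli or trials), or a `vg_features`.
#' @param labels logical vocal labels (taken from `X` if a `vg_features`).
#' @param cfg a [voice_config()].
#' @param seed seed controlling fold assignment and inner CV.
#' @return Object of class `vg_decoding`: `balanced_accuracy`, per-fold
#'   accuracies, selected `lambda` per fold, pooled `confusion`.
#' @export
fit_l1_logistic_cv <- function(X, labels = NULL, cfg = voice_config(),
                               seed = NULL) {
  if (inherits(X, "vg_features")) {
    labels <- X$labels
    X <- X$X
  }
  labels <- as.logical(labels)
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$n_outer_folds
  if (min(table(labels)) < k) {
    stop("stratification error: a class has fewer members than outer folds")
  }
  fold <- stratified_folds(labels, k)
  conf <- matrix(0, 2, 2)
  fold_acc <- lambdas <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    zs <- train_zscore(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    sel <- select_l1_model(zs$train, labels[!te], cfg)
    pr <- as.vector(stats::predict(sel$fit, pad_single_col(zs$other),
      s = sel$lambda, type = "response"
    ))
    pred <- pr >= 0.5
    conf_f <- table(
      factor(labels[te], levels = c(FALSE, TRUE)),
      factor(pred, levels = c(FALSE, TRUE))
    )
    conf <- conf + unclass(conf_f)
    fold_acc[f] <- balanced_accuracy_confusion(unclass(conf_f))
    lambdas[f] <- sel$lambda
  }
  structure(
    list(
      balanced_accuracy = balanced_accuracy_confusion(conf),
      fold_accuracy = fold_acc, lambda = lambdas, confusion = conf
    ),
    class = "vg_decoding"
  )
}

# Sliding-window balanced accuracies over a list of per-window column index
# sets of a full feature matrix.
sliding_accuracy <- function(data, labels, cfg) {
  vapply(data$window_cols, function(cols) {
    fit_l1_logistic_cv(data$X[, cols, drop = FALSE], labels, cfg)$balanced_accuracy
  }, numeric(1))
}

#' Sliding-window decoding with cluster-based significance
#'
#' Fits one decoding model per time window and assesses significance with
#' the one-sided (upper-tail) cluster permutation test on the accuracy
#' series: per-window critical values are the upper 95th percentile of the
#' label-permutation null, suprathreshold accuracies are summed into cluster
#' masses, and cluster p-values come from the permutation distribution of
#' maximum cluster masses.
#'
#' @param feats a `vg_features` built with `windows = "all"`.
#' @param cfg a [voice_config()].
#' @param n_perm permutations (default `cfg$n_perm_decoding`).
#' @param seed seed for folds and permutations.
#' @return List with `accuracy` (a [time_stat_series()]) and `clusters`
#'   (a `vg_clusters`).
#' @export
decode_sliding <- function(feats, cfg = voice_config(),
                           n_perm = cfg$n_perm_decoding, seed = NULL) {
  stopifnot(inherits(feats, "vg_features"))
  nw <- length(feats$centers_ms)
  nch <- length(feats$channel_ids)
  # channel-major, window-minor layout
  window_cols <- lapply(seq_len(nw), function(w) seq(w, by = nw, length.out = nch))
  data <- list(X = feats$X, window_cols = window_cols)
  res <- permutation_cluster_test(
    function(d, l) sliding_accuracy(d, l, cfg),
    data, feats$labels,
    n_perm = n_perm,
    window_alpha = cfg$cluster_window_alpha,
    alternative = "greater", seed = seed, time_ms = feats$centers_ms
  )
  list(
    accuracy = time_stat_series(res$observed, feats$centers_ms, "accuracy"),
    clusters = res
  )
}

#' Cross-task decoding
#'
#' Trains a single model on all data of one task and tests it on all data of
#' the other, restricted to the common window grid: only windows fully
#' contained in the first `cfg$cross_task_max_ms` (550) ms, i.e. centers up
#' to 500 ms. Test features are z-scored with training-set statistics.
#'
#' @param feats_train,feats_test `vg_features` from the two tasks; both must
#'   carry the common window centers.
#' @param cfg a [voice_config()].
#' @param seed seed for the inner CV fold assignment.
#' @return A `vg_decoding` with the test-task balanced accuracy.
#' @export
decode_cross_task <- function(feats_train, feats_test, cfg = voice_config(),
                              seed = NULL) {
  stopifnot(inherits(feats_train, "vg_features"), inherits(feats_test, "vg_features"))
  half <- cfg$window_width_ms / 2
  common <- function(f) {
    keep_w <- f$centers_ms + half <= cfg$cross_task_max_ms
    nw <- length(f$centers_ms)
    nch <- length(f$channel_ids)
    cols <- as.vector(outer(which(keep_w), (seq_len(nch) - 1) * nw, `+`))
    list(X = f$X[, cols, drop = FALSE], centers = f$centers_ms[keep_w])
  }
  tr <- common(feats_train)
  te <- common(feats_test)
  if (!identical(tr$centers, te$centers) ||
    length(feats_train$channel_ids) != length(feats_test$channel_ids)) {
    stop("window-grid mismatch between tasks")
  }
  if (!is.null(seed)) set.seed(seed)
  zs <- train_zscore(tr$X, te$X)
  sel <- select_l1_model(zs$train, feats_train$labels, cfg)
  pr <- as.vector(stats::predict(sel$fit, pad_single_col(zs$other),
    s = sel$lambda, type = "response"
  ))
  pred <- pr >= 0.5
  conf <- unclass(table(
    factor(feats_test$labels, levels = c(FALSE, TRUE)),
    factor(pred, levels = c(FALSE, TRUE))
  ))
  structure(
    list(
      balanced_accuracy = balanced_accuracy_confusion(conf),
      fold_accuracy = NULL, lambda = sel$lambda, confusion = conf,
      predicted = pred, probability = pr
    ),
    class = "vg_decoding"
  )
}

#' Permutation significance of full-model decoding
#'
#' Label-shuffle null of the full cross-validated balanced accuracy with a
#' complete refit per permutation; `p = (1 + #{null >= observed}) /
#' (1 + n_perm)`, optionally Bonferroni-corrected for `m_bonferroni`
#' simultaneous models.
#'
#' @param X feature matrix or `vg_features`.
#' @param labels logical labels (from `X` if a `vg_features`).
#' @param cfg a [voice_config()].
#' @param n_perm number of permutations (>= 100).
#' @param seed random seed.
#' @param m_bonferroni number of simultaneous models.
#' @return List with `observed`, `p`, `p_bonf`, `null` (the null accuracies).
#' @export
permutation_significance_full <- function(X, labels = NULL,
                                          cfg = voice_config(),
                                          n_perm = 1000, seed = NULL,
                                          m_bonferroni = 1) {
  if (inherits(X, "vg_features")) {
    labels <- X$labels
    X <- X$X
  }
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  obs <- fit_l1_logistic_cv(X, labels, cfg)$balanced_accuracy
  null <- vapply(seq_len(n_perm), function(i) {
    fit_l1_logistic_cv(X, sample(labels), cfg)$balanced_accuracy
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  list(
    observed = obs, p = p, p_bonf = min(1, p * m_bonferroni),
    null = null
  )
}
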