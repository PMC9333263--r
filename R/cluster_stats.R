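#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR correction used for channel selection. Adjustment is delegated
#' to [stats::p.adjust()]; rejection is at `adjusted < alpha`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with logical `rejected` and numeric `adjusted`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (!length(p)) stop("p must be non-empty")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p, method = "BH")
  list(rejected = adjusted < alpha, adjusted = adjusted)
}

#' Time-resolved statistic series
#'
#' Lightweight container for a statistic evaluated on a regular time grid
#' (per-sample t-statistics or per-window decoding accuracies).
#'
#' @param values numeric vector of statistics.
#' @param time_ms window/sample centers in ms relative to stimulus onset.
#' @param kind `"tstat"` or `"accuracy"`.
#' @return Object of class `vg_series`.
#' @export
time_stat_series <- function(values, time_ms, kind = c("tstat", "accuracy")) {
  kind <- match.arg(kind)
  if (length(values) != length(time_ms)) {
    stop("values and time_ms lengths differ")
  }
  if (any(!is.finite(values))) stop("statistic values must be finite")
  structure(list(values = values, time_ms = time_ms, kind = kind),
    class = "vg_series"
  )
}

series_values <- function(x) if (inherits(x, "vg_series")) x$values else x

#' Sliding two-sample t-statistics for one channel
#'
#' Student (pooled-variance) two-sample t at each time sample of a
#' single-channel trials-by-time matrix, vocal minus nonvocal. This is the
#' statistic entering the single-channel separability cluster test.
#'
#' @param x trials x time numeric matrix of single-trial HGA for one channel.
#' @param labels logical vector (TRUE = vocal) per trial.
#' @param time_ms optional time axis; defaults to column indices.
#' @return A [time_stat_series()] of kind `"tstat"`.
#' @export
sliding_tstats <- function(x, labels, time_ms = NULL) {
  x <- as.matrix(x)
  labels <- as.logical(labels)
  if (nrow(x) != length(labels)) stop("labels length must match trial count")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 < 2 || n0 < 2) stop("each class needs >= 2 trials")
  if (is.null(time_ms)) time_ms <- seq_len(ncol(x))
  x1 <- x[labels, , drop = FALSE]
  x0 <- x[!labels, , drop = FALSE]
  m1 <- colMeans(x1)
  m0 <- colMeans(x0)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  tt <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  time_stat_series(tt, time_ms, "tstat")
}

# Maximal runs of TRUE in a logical vector -> start/end index pairs.
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Form clusters of a series given per-window critical values; returns a
# data.frame of clusters with mass = sum of statistic values in the run.
form_clusters <- function(values, crit_hi, crit_lo = NULL) {
  out <- list()
  pos <- runs_of(values > crit_hi)
  if (nrow(pos)) {
    out[[1]] <- data.frame(
      start = pos[, 1], end = pos[, 2],
      mass = vapply(
        seq_len(nrow(pos)),
        function(i) sum(values[pos[i, 1]:pos[i, 2]]), numeric(1)
      )
    )
  }
  if (!is.null(crit_lo)) {
    neg <- runs_of(values < crit_lo)
    if (nrow(neg)) {
      out[[length(out) + 1]] <- data.frame(
        start = neg[, 1], end = neg[, 2],
        mass = vapply(
          seq_len(nrow(neg)),
          function(i) sum(values[neg[i, 1]:neg[i, 2]]), numeric(1)
        )
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), mass = numeric()))
  }
  cl <- do.call(rbind, out)
  cl[order(cl$start), , drop = FALSE]
}

#' Cluster-based permutation test over a time-resolved statistic
#'
#' Generic engine shared by sliding-window decoding and single-channel
#' separability. Labels are permuted `n_perm` times; at each window the
#' critical value is the upper `1 - window_alpha` percentile of that window's
#' permutation null (for two-sided statistics, the `1 - window_alpha/2` and
#' `window_alpha/2` percentiles bound positive and negative exceedances
#' separately). Observed clusters are maximal runs of windows exceeding their
#' critical value; a cluster's mass is the sum of the statistic over the run,
#' and its p-value is the fraction of permutation maximum-cluster-masses that
#' reach or exceed it. Permutations with no suprathreshold window contribute
#' mass 0.
#'
#' @param series_fn function `(data, labels) ->` numeric vector or
#'   [time_stat_series()], evaluated on observed and permuted labels.
#' @param data opaque data object forwarded to `series_fn`.
#' @param labels logical/two-level label vector to permute.
#' @param n_perm number of permutations (>= 100).
#' @param window_alpha per-window threshold level.
#' @param alternative `"greater"` for one-sided statistics (accuracy),
#'   `"two.sided"` for signed statistics (t).
#' @param seed random seed for the permutation stream.
#' @param perm_labels optional matrix (`n_perm` x `length(labels)`) of
#'   pre-built label arrangements, e.g. the exhaustive enumeration on small
#'   instances; overrides random shuffling.
#' @param time_ms optional time axis for reporting cluster extents.
#'
#' @return Object of class `vg_clusters`: a list with `clusters` (data.frame
#'   `start`, `end`, `start_ms`, `end_ms`, `mass`, `p`), `observed` series,
#'   `crit_hi`/`crit_lo`, `null_max_mass`, and `n_perm`.
#' @export
permutation_cluster_test <- function(series_fn, data, labels, n_perm = 1000,
                                     window_alpha = 0.05,
                                     alternative = c("greater", "two.sided"),
                                     seed = NULL, perm_labels = NULL,
                                     time_ms = NULL) {
  alternative <- match.arg(alternative)
  if (length(unique(labels)) < 2) {
    stop("labels must contain two classes")
  }
  if (is.null(perm_labels) && n_perm < 100) {
    stop("n_perm must be >= 100")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- series_fn(data, labels)
  if (inherits(obs, "vg_series") && is.null(time_ms)) time_ms <- obs$time_ms
  obs_v <- series_values(obs)
  nw <- length(obs_v)
  if (is.null(time_ms)) time_ms <- seq_len(nw)

  if (is.null(perm_labels)) {
    perm_labels <- t(vapply(
      seq_len(n_perm), function(i) sample(labels),
      labels
    ))
  } else {
    perm_labels <- as.matrix(perm_labels)
    n_perm <- nrow(perm_labels)
  }
  null_mat <- t(vapply(
    seq_len(n_perm),
    function(i) series_values(series_fn(data, perm_labels[i, ])),
    numeric(nw)
  ))

  if (alternative == "greater") {
    crit_hi <- apply(null_mat, 2, stats::quantile, probs = 1 - window_alpha)
    crit_lo <- NULL
  } else {
    crit_hi <- apply(null_mat, 2, stats::quantile, probs = 1 - window_alpha / 2)
    crit_lo <- apply(null_mat, 2, stats::quantile, probs = window_alpha / 2)
  }

  max_mass <- function(v) {
    cl <- form_clusters(v, crit_hi, crit_lo)
    if (!nrow(cl)) 0 else max(abs(cl$mass))
  }
  null_max <- vapply(seq_len(n_perm), function(i) max_mass(null_mat[i, ]),
    numeric(1)
  )

  clusters <- form_clusters(obs_v, crit_hi, crit_lo)
  if (nrow(clusters)) {
    clusters$p <- vapply(
      clusters$mass,
      function(m) mean(null_max >= abs(m)), numeric(1)
    )
    clusters$start_ms <- time_ms[clusters$start]
    clusters$end_ms <- time_ms[clusters$end]
    clusters <- clusters[, c("start", "end", "start_ms", "end_ms", "mass", "p")]
  } else {
    clusters <- data.frame(
      start = integer(), end = integer(),
      start_ms = numeric(), end_ms = numeric(),
      mass = numeric(), p = numeric()
    )
  }
  structure(
    list(
      clusters = clusters, observed = obs_v, time_ms = time_ms,
      crit_hi = crit_hi, crit_lo = crit_lo, null_max_mass = null_max,
      n_perm = n_perm, window_alpha = window_alpha,
      alternative = alternative
    ),
    class = "vg_clusters"
  )
}

#' Sum of significant cluster masses
#'
#' The separability metric: the sum of absolute masses over all clusters with
#' permutation p below `p_threshold`, or 0 when there are none. Summing over
#' all significant clusters (rather than taking the maximum) credits channels
#' whose separability recurs in several disjoint bursts.
#'
#' @param result a `vg_clusters` object.
#' @param p_threshold cluster significance level (default 0.001).
#' @return Nonnegative scalar.
#' @export
sum_cluster_mass <- function(result, p_threshold = 0.001) {
  stopifnot(inherits(result, "vg_clusters"))
  cl <- result$clusters
  if (!nrow(cl)) return(0)
  sig <- cl$p < p_threshold
  if (!any(sig)) return(0)
  sum(abs(cl$mass[sig]))
}
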