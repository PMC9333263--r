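#' Reduce an acoustic feature table for encoding models
#'
#' Acoustic "functionals" features (per-stimulus statistical summaries of
#' frame-level descriptors) are highly collinear and heterogeneous in units,
#' so columns are standardized and reduced by principal component analysis;
#' the smallest number of leading components whose cumulative explained
#' variance reaches `cfg$pca_var_target` (99.99%) is kept, and the binary
#' vocal-category indicator is appended outside the PCA.
#'
#' @param features stimuli x m numeric matrix/data.frame with stimulus ids as
#'   row names.
#' @param vocal logical vocal flag per stimulus (same order as rows).
#' @param cfg a [voice_config()].
#' @param exclude_ids stimulus ids to drop before the PCA (e.g. acoustic
#'   outliers).
#' @return Object of class `vg_design`: list with `components` (stimuli x k
#'   score matrix), `vocal`, `k`, `explained` (cumulative variance fractions)
#'   and `stimulus_id`.
#' @export
reduce_features <- function(features, vocal, cfg = voice_config(),
                            exclude_ids = NULL) {
  X <- as.matrix(features)
  if (ncol(X) < 2) stop("need >= 2 feature columns")
  if (anyNA(X)) stop("feature table contains missing values")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  keep <- !(ids %in% exclude_ids)
  X <- X[keep, , drop = FALSE]
  ids <- ids[keep]
  vocal <- as.logical(vocal)[keep]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "degenerate (constant) feature column(s): ",
      paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", ")
    )
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= cfg$pca_var_target)[1]
  structure(
    list(
      components = pc$x[, seq_len(k), drop = FALSE],
      vocal = vocal, k = k, explained = cum, stimulus_id = ids
    ),
    class = "vg_design"
  )
}

# Design matrices (without intercept) for the full and acoustic-only models.
design_matrix <- function(design, with_category) {
  if (with_category) {
    cbind(design$components, vocal = as.numeric(design$vocal))
  } else {
    design$components
  }
}

#' Leave-one-out cross-validated R-squared
#'
#' Out-of-sample fit of an ordinary least-squares model, computed exactly via
#' the closed-form leverage identity `e_i / (1 - h_ii)` for the leave-one-out
#' residuals: `R2 = 1 - SS_loo / SS_tot`.
#'
#' @param X predictor matrix (no intercept column; one is added).
#' @param y response vector.
#' @return Scalar LOOCV R-squared (can be negative).
#' @export
loocv_r2 <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  Xi <- cbind(1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) stop("rank-deficient design")
  e <- stats::lm.fit(Xi, y)$residuals
  h <- rowSums(qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]^2)
  loo <- e / (1 - h)
  1 - sum(loo^2) / sum((y - mean(y))^2)
}

#' Permutation significance of the LOOCV R-squared
#'
#' Null distribution obtained by shuffling the rows of the predictor matrix
#' (breaking the stimulus-response pairing while preserving the feature
#' covariance); `p = (1 + #{null >= observed}) / (1 + n_perm)` with optional
#' Bonferroni correction across channels x windows.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param n_perm number of permutations (>= 100).
#' @param seed random seed.
#' @param m_bonferroni number of simultaneous tests.
#' @return List with `observed`, `p`, `p_bonf`.
#' @export
r2_significance <- function(X, y, n_perm = 1000, seed = NULL,
                            m_bonferroni = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  obs <- loocv_r2(X, y)
  null <- vapply(seq_len(n_perm), function(i) {
    loocv_r2(X[sample(nrow(X)), , drop = FALSE], y)
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  list(observed = obs, p = p, p_bonf = min(1, p * m_bonferroni))
}

#' Likelihood-ratio test for the vocal-category feature
#'
#' Compares the full linear model (acoustic components + vocal indicator) to
#' the nested acoustic-only model, both fit by least squares on the full
#' stimulus set. With the Gaussian error variance profiled out, the statistic
#' is `chi2 = n * ln(RSS_nested / RSS_full) = 2 (LL_full - LL_nested)`,
#' chi-squared with 1 degree of freedom under the null (one added
#' regressor).
#'
#' @param design a `vg_design` from [reduce_features()].
#' @param y response vector (per-channel window-mean HGA).
#' @return List with `chi2`, `p`, `rss_full`, `rss_nested`.
#' @export
lrt_category <- function(design, y) {
  stopifnot(inherits(design, "vg_design"))
  n <- length(y)
  Xf <- cbind(1, design_matrix(design, TRUE))
  Xn <- cbind(1, design_matrix(design, FALSE))
  rss_f <- sum(stats::lm.fit(Xf, y)$residuals^2)
  rss_n <- sum(stats::lm.fit(Xn, y)$residuals^2)
  if (rss_f <= 0) stop("degenerate fit: zero residual sum of squares")
  chi2 <- max(0, n * log(rss_n / rss_f))
  list(
    chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    rss_full = rss_f, rss_nested = rss_n
  )
}

#' Fit encoding models for a set of channels
#'
#' For each channel and response window (onset, sustained): LOOCV R-squared
#' of the full (acoustics + category) and acoustic-only models, permutation
#' significance of the full-model R-squared (Bonferroni across channels x
#' windows), and the likelihood-ratio chi-squared for the category feature.
#'
#' @param design a `vg_design`.
#' @param responses named list with elements `onset` and `sustained`, each a
#'   stimuli x channels matrix of window-mean HGA (stimulus order matching
#'   `design$stimulus_id`).
#' @param n_perm permutations for R-squared significance.
#' @param seed random seed.
#' @return data.frame, one row per channel x window, with `channel`,
#'   `window`, `r2_full`, `r2_acoustic`, `r2_p_bonf`, `lrt_chi2`, `lrt_p`.
#' @export
fit_encoding_models <- function(design, responses, n_perm = 1000,
                                seed = NULL) {
  stopifnot(inherits(design, "vg_design"))
  Xf <- design_matrix(design, TRUE)
  Xa <- design_matrix(design, FALSE)
  windows <- names(responses)
  m <- sum(vapply(responses, ncol, integer(1)))
  rows <- list()
  for (w in windows) {
    Y <- responses[[w]]
    if (nrow(Y) != nrow(Xf)) stop("response rows must match design rows")
    for (ch in seq_len(ncol(Y))) {
      y <- Y[, ch]
      sig <- r2_significance(Xf, y,
        n_perm = n_perm,
        seed = if (is.null(seed)) NULL else seed + ch * 7919 + match(w, windows),
        m_bonferroni = m
      )
      lrt <- lrt_category(design, y)
      rows[[length(rows) + 1]] <- data.frame(
        channel = if (!is.null(colnames(Y))) colnames(Y)[ch] else as.character(ch),
        window = w,
        r2_full = sig$observed,
        r2_acoustic = loocv_r2(Xa, y),
        r2_p_bonf = sig$p_bonf,
        lrt_chi2 = lrt$chi2, lrt_p = lrt$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROI contrasts of encoding-model metrics
#'
#' Rank-sum contrasts of the likelihood-ratio chi-squared and of the full and
#' acoustic-only R-squared values between the STP and STG/STS super-ROIs,
#' separately per response window.
#'
#' @param fits data.frame from [fit_encoding_models()].
#' @param channel_roi named character vector mapping channel id to super-ROI.
#' @return data.frame with one row per window x metric: `window`, `metric`,
#'   `statistic`, `p`, `direction` (sign of STG/STS minus STP median).
#' @export
classify_channels <- function(fits, channel_roi) {
  roi <- channel_roi[fits$channel]
  if (anyNA(roi)) stop("channel(s) without ROI label")
  rows <- list()
  for (w in unique(fits$window)) {
    sel <- fits$window == w & roi %in% c("STP", "STG/STS")
    g <- roi[sel] == "STG/STS"
    if (sum(g) < 2 || sum(!g) < 2) stop("need >= 2 channels per super-ROI")
    for (metric in c("lrt_chi2", "r2_full", "r2_acoustic")) {
      x <- fits[[metric]][sel]
      ht <- stats::wilcox.test(x[g], x[!g], exact = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        window = w, metric = metric,
        statistic = unname(ht$statistic), p = ht$p.value,
        direction = sign(stats::median(x[g]) - stats::median(x[!g])),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
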