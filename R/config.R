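#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default value. All
#' analysis windows are half-open `[start, end)` in milliseconds relative to
#' stimulus onset; all sample indices are 0-based.
#'
#' @param ... name-value pairs overriding the defaults listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{epoch_pre_ms}{1000 — epoch start before stimulus onset (ms).}
#'   \item{epoch_post_offset_ms}{`c(VL = 1450, NatS = 1000)` — epoch end
#'     after stimulus offset, per task (ms).}
#'   \item{baseline_window_ms}{`c(-600, -100)` — silent baseline used for
#'     the auditory-responsiveness t-test.}
#'   \item{hga_band_hz}{`c(70, 150)` — broadband high-gamma edges; centers
#'     of the filter bank are log-spaced across this range.}
#'   \item{filter_order}{6 — Butterworth bandpass order (applied
#'     forward-and-reverse, so effectively 12th order, zero phase).}
#'   \item{n_bands}{8 — number of bandpass filters in the bank.}
#'   \item{bandwidth_range_hz}{`c(16, 64)` — log-spaced bandwidths.}
#'   \item{hga_rate_hz}{100 — output rate of the HGA series.}
#'   \item{clip_pre_ms, clip_post_offset_ms}{900/900 — HGA series clip
#'     bounds around onset/offset.}
#'   \item{baseline_edge_discard_ms}{100 — amount of baseline discarded at
#'     both ends when computing band-normalization statistics.}
#'   \item{onset_window_ms, sustained_window_ms}{`c(0, 500)` and
#'     `c(500, 2000)` — the two response windows.}
#'   \item{window_width_ms, window_step_ms}{100/50 — sliding decoding
#'     windows.}
#'   \item{window_center_range_ms}{`list(VL = c(-50, 1500), NatS =
#'     c(-50, 2450))` — sliding-window center grids per task.}
#'   \item{cross_task_max_ms}{550 — cross-task models use only windows
#'     fully contained in the first 550 ms.}
#'   \item{n_perm_decoding, n_perm_single, n_perm_encoding}{1000 / 10000 /
#'     10000 permutations.}
#'   \item{cluster_window_alpha}{0.05 — per-window threshold percentile of
#'     the permutation null.}
#'   \item{cluster_p_threshold}{0.001 — cluster significance level entering
#'     the sum-cluster-mass separability metric.}
#'   \item{alpha_fdr}{0.05 — BH-FDR level for channel selection.}
#'   \item{pca_var_target}{0.9999 — cumulative explained-variance target
#'     for acoustic feature reduction.}
#'   \item{n_lambda, lambda_min_ratio}{20 / 1e-3 — L1 regularization path.}
#'   \item{n_outer_folds, n_inner_folds}{5 / 10 — nested cross-validation.}
#'   \item{band_norm_pool_channels}{FALSE — band z-normalization statistics
#'     are per channel (set TRUE to pool across channels).}
#'   \item{seed}{1 — default random seed.}
#' }
#'
#' @return A list of class `voice_config`.
#' @export
voice_config <- function(...) {
  cfg <- list(
    epoch_pre_ms = 1000,
    epoch_post_offset_ms = c(VL = 1450, NatS = 1000),
    baseline_window_ms = c(-600, -100),
    hga_band_hz = c(70, 150),
    filter_order = 6,
    n_bands = 8,
    bandwidth_range_hz = c(16, 64),
    hga_rate_hz = 100,
    clip_pre_ms = 900,
    clip_post_offset_ms = 900,
    baseline_edge_discard_ms = 100,
    onset_window_ms = c(0, 500),
    sustained_window_ms = c(500, 2000),
    window_width_ms = 100,
    window_step_ms = 50,
    window_center_range_ms = list(VL = c(-50, 1500), NatS = c(-50, 2450)),
    cross_task_max_ms = 550,
    n_perm_decoding = 1000,
    n_perm_single = 10000,
    n_perm_encoding = 10000,
    cluster_window_alpha = 0.05,
    cluster_p_threshold = 0.001,
    alpha_fdr = 0.05,
    pca_var_target = 0.9999,
    n_lambda = 20,
    lambda_min_ratio = 1e-3,
    n_outer_folds = 5,
    n_inner_folds = 10,
    band_norm_pool_channels = FALSE,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown or unnamed config fields: ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  for (a in c("cluster_window_alpha", "cluster_p_threshold", "alpha_fdr")) {
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1) stop(a, " must lie in (0, 1)")
  }
  if (cfg$n_bands < 2) stop("n_bands must be >= 2")
  structure(cfg, class = "voice_config")
}

# Task lookup helpers shared by epoching and feature building.
task_post_offset_ms <- function(cfg, task) {
  v <- cfg$epoch_post_offset_ms[[task]]
  if (is.null(v)) stop("unknown task: ", task)
  v
}

task_center_range_ms <- function(cfg, task) {
  v <- cfg$window_center_range_ms[[task]]
  if (is.null(v)) stop("unknown task: ", task)
  v
}
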