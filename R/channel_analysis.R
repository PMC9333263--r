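#' Auditory responsiveness per channel
#'
#' For every channel, mean HGA over the post-onset window `[0, 500)` ms and
#' the silent baseline `[-600, -100)` ms is computed per trial; the two sets
#' of trial means are compared with a two-sample (pooled-variance) t-test.
#' P-values are BH-FDR corrected across channels and channels with corrected
#' p below `cfg$alpha_fdr` are flagged responsive.
#'
#' @param hga a `vg_hga` object.
#' @param cfg a [voice_config()].
#' @return data.frame with `channel_id`, `t`, `p`, `p_fdr`, `responsive`.
#' @export
auditory_responsiveness <- function(hga, cfg = voice_config()) {
  stopifnot(inherits(hga, "vg_hga"))
  if (dim(hga$data)[1] < 2) stop("need >= 2 trials")
  post <- which(hga$time_ms >= cfg$onset_window_ms[1] &
    hga$time_ms < cfg$onset_window_ms[2])
  base <- which(hga$time_ms >= cfg$baseline_window_ms[1] &
    hga$time_ms < cfg$baseline_window_ms[2])
  if (!length(post) || !length(base)) {
    stop("responsiveness windows fall outside the epoch")
  }
  nc <- dim(hga$data)[2]
  tt <- pp <- numeric(nc)
  for (ch in seq_len(nc)) {
    a <- rowMeans(hga$data[, ch, post, drop = FALSE], dims = 1)
    b <- rowMeans(hga$data[, ch, base, drop = FALSE], dims = 1)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      stop("degenerate (constant) HGA in channel ", hga$channels$channel_id[ch])
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tt[ch] <- unname(ht$statistic)
    pp[ch] <- ht$p.value
  }
  fdr <- bh_fdr(pp, cfg$alpha_fdr)
  data.frame(
    channel_id = hga$channels$channel_id, t = tt, p = pp,
    p_fdr = fdr$adjusted, responsive = fdr$rejected,
    stringsAsFactors = FALSE
  )
}

#' Vocal/nonvocal separability of one channel
#'
#' Runs the cluster-based permutation test on the time-resolved two-sample
#' t-statistic (vocal minus nonvocal) of single-trial responses, two-sided,
#' and quantifies separability as the sum of masses of all significant
#' clusters (p below `cfg$cluster_p_threshold`).
#'
#' @param x trials x time matrix of single-trial HGA for one channel.
#' @param labels logical vocal flag per trial.
#' @param cfg a [voice_config()].
#' @param n_perm number of permutations; defaults to `cfg$n_perm_single`.
#' @param seed permutation seed.
#' @param time_ms time axis of `x` (ms).
#' @return List with `separability` (nonnegative scalar), `clusters` (a
#'   `vg_clusters` object), and `onset_ms` (start of the earliest significant
#'   cluster, or NA).
#' @export
vnv_separability <- function(x, labels, cfg = voice_config(),
                             n_perm = cfg$n_perm_single, seed = NULL,
                             time_ms = NULL) {
  res <- permutation_cluster_test(
    function(d, l) sliding_tstats(d, l, time_ms),
    x, labels,
    n_perm = n_perm, window_alpha = cfg$cluster_window_alpha,
    alternative = "two.sided", seed = seed, time_ms = time_ms
  )
  sep <- sum_cluster_mass(res, cfg$cluster_p_threshold)
  sig <- res$clusters$p < cfg$cluster_p_threshold
  onset <- if (any(sig)) min(res$clusters$start_ms[sig]) else NA_real_
  list(separability = sep, clusters = res, onset_ms = onset)
}

#' Category-by-window mean HGA
#'
#' Means of stimulus responses over the onset `[0, 500)` and sustained
#' `[500, 2000)` windows, then over stimuli within the vocal and nonvocal
#' categories.
#'
#' @param resp a `vg_stim_response` (NatS-length responses).
#' @param stimuli stimulus table (defaults to the one carried by `resp`).
#' @param cfg a [voice_config()].
#' @return Numeric array channels x category (`V`, `NV`) x window
#'   (`onset`, `sustained`), in baseline-z units.
#' @export
window_means <- function(resp, stimuli = resp$stimuli, cfg = voice_config()) {
  stopifnot(inherits(resp, "vg_stim_response"))
  if (!any(stimuli$vocal) || !any(!stimuli$vocal)) {
    stop("both vocal and nonvocal stimuli are required")
  }
  wins <- list(onset = cfg$onset_window_ms, sustained = cfg$sustained_window_ms)
  nc <- dim(resp$data)[2]
  out <- array(NA_real_,
    dim = c(nc, 2, 2),
    dimnames = list(
      resp$channels$channel_id, c("V", "NV"),
      names(wins)
    )
  )
  for (w in seq_along(wins)) {
    idx <- which(resp$time_ms >= wins[[w]][1] & resp$time_ms < wins[[w]][2])
    if (!length(idx)) stop("window ", names(wins)[w], " outside response")
    for (ch in seq_len(nc)) {
      per_stim <- rowMeans(resp$data[, ch, idx, drop = FALSE], dims = 1)
      out[ch, "V", w] <- mean(per_stim[stimuli$vocal])
      out[ch, "NV", w] <- mean(per_stim[!stimuli$vocal])
    }
  }
  out
}

#' Vocal category preference strength (HGA ratio)
#'
#' `r = (V - NV) / (V + NV)` on window-mean HGA responses. Negative means
#' (responses below baseline) are clipped to 0 before the ratio so the
#' result is bounded in `[-1, 1]`; the degenerate 0/0 case is defined as 0
#' (no preference). A value of 1 (or -1) marks a channel responding only to
#' vocal (or nonvocal) stimuli; 0 marks equal responses. The ratio is
#' invariant to overall response scaling.
#'
#' @param hga_v,hga_nv mean HGA for vocal / nonvocal stimuli (vectorized).
#' @return Numeric vector in `[-1, 1]`.
#' @export
hga_ratio <- function(hga_v, hga_nv) {
  if (any(!is.finite(hga_v)) || any(!is.finite(hga_nv))) {
    stop("hga_ratio inputs must be finite")
  }
  v <- pmax(hga_v, 0)
  nv <- pmax(hga_nv, 0)
  s <- v + nv
  ifelse(s == 0, 0, (v - nv) / s)
}

#' Median separability onset within an ROI
#'
#' Separability onset is noise-sensitive: weakly separable channels cross the
#' cluster threshold late. The estimate therefore uses only the 50% most
#' separable channels of the ROI (`ceiling(n/2)` channels, ties broken by
#' channel id) and reports the median of their earliest significant cluster
#' start times.
#'
#' @param stats per-channel data.frame with columns `channel_id`,
#'   `super_roi`, `separability`, `onset_ms`.
#' @param roi `"STP"` or `"STG/STS"`.
#' @return Median onset in ms, or `NA` (with a warning) when no separable
#'   channel exists in the ROI.
#' @export
separability_onset <- function(stats, roi) {
  d <- stats[stats$super_roi == roi & stats$separability > 0 &
    !is.na(stats$onset_ms), , drop = FALSE]
  if (!nrow(d)) {
    warning("no separable channels in ROI ", roi)
    return(NA_real_)
  }
  if (nrow(d) == 1) {
    warning("single separable channel in ROI ", roi)
    return(d$onset_ms)
  }
  d <- d[order(-d$separability, d$channel_id), , drop = FALSE]
  top <- d[seq_len(ceiling(nrow(d) / 2)), , drop = FALSE]
  stats::median(top$onset_ms)
}

#' ROI and window contrasts of channel statistics
#'
#' Unpaired contrasts (STP vs STG/STS, left vs right) use the Wilcoxon
#' rank-sum test; the paired onset-vs-sustained contrast uses the Wilcoxon
#' sign-rank test; contrasts of proportions (a logical metric, e.g.
#' separable yes/no) use Fisher's exact test on the pooled 2x2 table.
#' Channels with super-ROI `other` are excluded.
#'
#' @param stats per-channel data.frame with `super_roi`, `hemisphere`, and
#'   the metric column(s).
#' @param metric column name; for `grouping = "window"`, supply the two
#'   paired column names `c(onset_col, sustained_col)`.
#' @param grouping `"roi"`, `"window"`, or `"hemisphere"`.
#' @return List with `statistic`, `p`, and `method`.
#' @export
roi_compare <- function(stats, metric,
                        grouping = c("roi", "window", "hemisphere")) {
  grouping <- match.arg(grouping)
  if (grouping == "window") {
    if (length(metric) != 2) {
      stop("window contrast needs the two paired metric columns")
    }
    a <- stats[[metric[1]]]
    b <- stats[[metric[2]]]
    if (length(a) < 2) stop("need >= 2 paired observations")
    ht <- stats::wilcox.test(b, a, paired = TRUE, exact = FALSE)
    return(list(
      statistic = unname(ht$statistic), p = ht$p.value,
      method = "sign-rank"
    ))
  }
  d <- stats[stats$super_roi %in% c("STP", "STG/STS"), , drop = FALSE]
  g <- if (grouping == "roi") {
    d$super_roi == "STG/STS"
  } else {
    d$hemisphere == "right"
  }
  x <- d[[metric]]
  if (is.null(x)) stop("unknown metric column: ", metric)
  if (sum(g) < 2 || sum(!g) < 2) stop("need >= 2 observations per group")
  if (is.logical(x)) {
    tab <- table(group = g, metric = x)
    ht <- stats::fisher.test(tab)
    return(list(
      statistic = unname(ht$estimate), p = ht$p.value,
      method = "fisher-exact"
    ))
  }
  ht <- stats::wilcox.test(x[g], x[!g], exact = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value, method = "rank-sum")
}

#' Full per-channel statistics table
#'
#' Convenience pipeline stage: auditory responsiveness for every channel,
#' then, for responsive channels, V-NV separability (cluster permutation on
#' single trials), onset/sustained window means on stimulus responses, and
#' HGA ratios.
#'
#' @param hga a `vg_hga` (single-trial responses).
#' @param resp the matching `vg_stim_response`.
#' @param stimuli stimulus table.
#' @param cfg a [voice_config()].
#' @param n_perm permutations for the separability test.
#' @param seed permutation seed.
#' @return data.frame, one row per channel: responsiveness columns plus
#'   `separability`, `onset_ms`, the four window means, and
#'   `hga_ratio_onset` / `hga_ratio_sustained` (NA for non-responsive
#'   channels).
#' @export
compute_channel_stats <- function(hga, resp, stimuli = resp$stimuli,
                                  cfg = voice_config(),
                                  n_perm = cfg$n_perm_single, seed = NULL) {
  ar <- auditory_responsiveness(hga, cfg)
  wm <- window_means(resp, stimuli, cfg)
  labels <- stimuli$vocal[match(hga$trials$stimulus_id, stimuli$stimulus_id)]
  nc <- nrow(ar)
  sep <- onset <- rep(NA_real_, nc)
  for (ch in which(ar$responsive)) {
    vs <- vnv_separability(hga$data[, ch, ], labels, cfg,
      n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + ch,
      time_ms = hga$time_ms
    )
    sep[ch] <- vs$separability
    onset[ch] <- vs$onset_ms
  }
  out <- data.frame(
    ar,
    super_roi = hga$channels$super_roi,
    hemisphere = hga$channels$hemisphere,
    separability = sep, onset_ms = onset,
    mean_v_onset = wm[, "V", "onset"],
    mean_nv_onset = wm[, "NV", "onset"],
    mean_v_sustained = wm[, "V", "sustained"],
    mean_nv_sustained = wm[, "NV", "sustained"],
    stringsAsFactors = FALSE
  )
  out$hga_ratio_onset <- hga_ratio(out$mean_v_onset, out$mean_nv_onset)
  out$hga_ratio_sustained <- hga_ratio(
    out$mean_v_sustained,
    out$mean_nv_sustained
  )
  rownames(out) <- NULL
  out
}
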