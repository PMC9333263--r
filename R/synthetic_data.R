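#' Synthetic channel specification
#'
#' Describes the designed response of one simulated sEEG channel. Gains are
#' high-gamma envelope amplitudes (in multiples of the carrier's baseline
#' amplitude) applied during the onset `[0, 500)` and sustained
#' `[500, duration)` response windows, separately for vocal and nonvocal
#' stimuli. Role defaults encode the channel archetypes seen in auditory
#' cortex: `category_encoder` (onset responses to both categories, sustained
#' response only to voice — the STG/STS archetype), `acoustic_encoder`
#' (equal category gains plus modulation by latent acoustic factors — the
#' STP archetype), and `nonresponsive` (all gains zero).
#'
#' @param role one of `"category_encoder"`, `"acoustic_encoder"`,
#'   `"nonresponsive"`.
#' @param onset_gain_v,onset_gain_nv,sustained_gain_v,sustained_gain_nv
#'   nonnegative envelope gains; defaults depend on `role`.
#' @param latency_ms nonnegative response latency.
#' @param acoustic_weights numeric vector of weights over the latent acoustic
#'   factors (gain modulation per unit factor score), or NULL.
#' @param noise_sd positive SD of the channel's 1/f background (microvolts).
#' @return List of class `vg_channel_spec`.
#' @export
channel_spec <- function(role = c(
                           "category_encoder", "acoustic_encoder",
                           "nonresponsive"
                         ),
                         onset_gain_v = NULL, onset_gain_nv = NULL,
                         sustained_gain_v = NULL, sustained_gain_nv = NULL,
                         latency_ms = 0, acoustic_weights = NULL,
                         noise_sd = 1) {
  role <- match.arg(role)
  defaults <- switch(role,
    category_encoder = c(3, 2, 3, 0),
    acoustic_encoder = c(3, 3, 3, 3),
    nonresponsive = c(0, 0, 0, 0)
  )
  g <- c(
    onset_gain_v %||% defaults[1], onset_gain_nv %||% defaults[2],
    sustained_gain_v %||% defaults[3], sustained_gain_nv %||% defaults[4]
  )
  if (any(g < 0)) stop("gains must be nonnegative")
  if (role == "nonresponsive" && any(g != 0)) {
    stop("nonresponsive channels must have all gains 0")
  }
  if (latency_ms < 0) stop("latency_ms must be nonnegative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(
    list(
      role = role,
      onset_gain_v = g[1], onset_gain_nv = g[2],
      sustained_gain_v = g[3], sustained_gain_nv = g[4],
      latency_ms = latency_ms, acoustic_weights = acoustic_weights,
      noise_sd = noise_sd
    ),
    class = "vg_channel_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Example stimulus table
#'
#' Builds a stimulus table with the design of the two tasks: NatS-like
#' (2000-ms natural sounds in 11 categories, 4 of them vocal, speech flags on
#' the speech/lyrical categories) or VL-like (550-ms clips, balanced vocal
#' and nonvocal classes).
#'
#' @param task `"NatS"` or `"VL"`.
#' @param n_vocal,n_nonvocal class sizes (defaults: 37/128 for NatS after
#'   reclassification, 72/72 for VL after balancing).
#' @param seed seed for category assignment.
#' @return A [stimulus_table()].
#' @export
example_stimulus_table <- function(task = c("NatS", "VL"), n_vocal = NULL,
                                   n_nonvocal = NULL, seed = 1) {
  task <- match.arg(task)
  set.seed(seed)
  if (task == "NatS") {
    n_vocal <- n_vocal %||% 37
    n_nonvocal <- n_nonvocal %||% 128
    voc_cats <- c(
      "english_speech", "foreign_speech", "human_vocal",
      "lyrical_music"
    )
    nv_cats <- c(
      "animal", "mechanical", "nature", "nonlyrical_music",
      "tools", "vehicles", "environmental"
    )
    cat_v <- sample(voc_cats, n_vocal, replace = TRUE)
    cat_nv <- sample(nv_cats, n_nonvocal, replace = TRUE)
    stimulus_table(
      stimulus_id = sprintf("nats_%03d", seq_len(n_vocal + n_nonvocal)),
      task = "NatS",
      category = c(cat_v, cat_nv),
      vocal = c(rep(TRUE, n_vocal), rep(FALSE, n_nonvocal)),
      speech = c(
        cat_v %in% c("english_speech", "foreign_speech", "lyrical_music"),
        rep(FALSE, n_nonvocal)
      )
    )
  } else {
    n_vocal <- n_vocal %||% 72
    n_nonvocal <- n_nonvocal %||% 72
    stimulus_table(
      stimulus_id = sprintf("vl_%03d", seq_len(n_vocal + n_nonvocal)),
      task = "VL",
      category = c(rep("vocal_clip", n_vocal), rep("nonvocal_clip", n_nonvocal)),
      vocal = c(rep(TRUE, n_vocal), rep(FALSE, n_nonvocal)),
      speech = FALSE
    )
  }
}

#' Generate a 1-back trial schedule
#'
#' Each stimulus is presented `n_presentations` times in shuffled order
#' (immediate duplicates from the shuffle are dispersed), then 1-back repeat
#' trials — flagged immediate re-presentations of the previous stimulus —
#' are inserted so that repeats make up about `repeat_fraction` of all
#' trials. Inter-stimulus intervals are uniform within `isi_bounds_ms`, so
#' successive onsets are separated by at least the stimulus duration plus
#' the lower ISI bound.
#'
#' @param stimuli a [stimulus_table()].
#' @param n_presentations minimum presentations per stimulus.
#' @param repeat_fraction target fraction of repeat trials, in `[0, 1)`.
#' @param isi_bounds_ms `(lower, upper)` ISI bounds in ms.
#' @param seed random seed.
#' @param lead_in_ms silence before the first onset (>= the epoch
#'   prestimulus span).
#' @return A [trial_table()].
#' @export
make_trial_schedule <- function(stimuli, n_presentations = 3,
                                repeat_fraction = 0.16,
                                isi_bounds_ms = c(1000, 2000), seed = 1,
                                lead_in_ms = 2000) {
  if (!nrow(stimuli)) stop("stimulus table is empty")
  if (repeat_fraction < 0 || repeat_fraction >= 1) {
    stop("repeat_fraction must lie in [0, 1)")
  }
  if (isi_bounds_ms[1] >= isi_bounds_ms[2]) {
    stop("isi lower bound must be below upper bound")
  }
  set.seed(seed)
  base <- sample(rep(stimuli$stimulus_id, n_presentations))
  # disperse accidental immediate duplicates so that is_repeat alone defines
  # the 1-back structure
  for (pass in 1:10) {
    dup <- which(base[-1] == base[-length(base)]) + 1
    if (!length(dup)) break
    for (i in dup) {
      j <- sample(length(base), 1)
      tmp <- base[i]
      base[i] <- base[j]
      base[j] <- tmp
    }
  }
  seq_ids <- character(0)
  rep_flag <- logical(0)
  p_insert <- if (repeat_fraction > 0) repeat_fraction / (1 - repeat_fraction) else 0
  for (s in base) {
    seq_ids <- c(seq_ids, s)
    rep_flag <- c(rep_flag, FALSE)
    if (p_insert > 0 && stats::runif(1) < p_insert) {
      seq_ids <- c(seq_ids, s)
      rep_flag <- c(rep_flag, TRUE)
    }
  }
  dur <- stimuli$duration_ms[1]
  isi <- stats::runif(length(seq_ids) - 1, isi_bounds_ms[1], isi_bounds_ms[2])
  onsets_ms <- lead_in_ms + cumsum(c(0, dur + isi))
  trial_table(
    trial_id = seq_along(seq_ids), stimulus_id = seq_ids,
    onset_sample = round(onsets_ms), is_repeat = rep_flag
  )
}

# 1/f (pink) noise by spectral shaping of white noise, standardized to unit
# SD.
onef_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # mirrored frequency index
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  (y - mean(y)) / stats::sd(y)
}

# Piecewise-linear envelope gain profile for one trial: ramp up over
# `ramp` ms, onset gain until 500 ms, linear transition to the sustained
# gain, ramp down at stimulus offset.
trial_gain_profile <- function(g_on, g_sus, duration_ms, onset_end_ms = 500,
                               ramp_ms = 50) {
  t <- seq_len(duration_ms) - 1
  g <- ifelse(t < onset_end_ms, g_on, g_sus)
  # transition between windows
  tr <- t >= onset_end_ms & t < onset_end_ms + ramp_ms
  g[tr] <- g_on + (g_sus - g_on) * (t[tr] - onset_end_ms) / ramp_ms
  up <- t < ramp_ms
  g[up] <- g[up] * t[up] / ramp_ms
  down <- t >= duration_ms - ramp_ms
  g[down] <- g[down] * (duration_ms - 1 - t[down]) / ramp_ms
  g
}

#' Synthesize a multichannel voltage recording
#'
#' Each channel is the sum of a 1/f background, an optional shared
#' common-mode 1/f component (removed by the common average reference), an
#' optional line-frequency sinusoid, and a band-limited (70-150 Hz)
#' carrier — bandpass-filtered white noise — whose amplitude envelope rises
#' multiplicatively by the channel's designed gain during the onset and
#' sustained windows of each trial, category-dependently, with 50-ms linear
#' ramps and the channel's latency. For channels with `acoustic_weights`,
#' the per-trial gain is additionally shifted by the dot product of the
#' weights with the stimulus's latent acoustic factors.
#'
#' @param specs list of [channel_spec()] objects.
#' @param trials a [trial_table()].
#' @param stimuli the matching [stimulus_table()].
#' @param common_noise_sd SD of the shared across-channel noise (0 = none).
#' @param line_hz optional line frequency (e.g. 60); amplitude 1.
#' @param seed random seed (all randomness derives from it).
#' @param acoustic_latent optional stimuli x factors matrix of latent
#'   acoustic scores (rows named by stimulus id) used by acoustic-encoder
#'   channels.
#' @param carrier_amp baseline carrier amplitude in microvolts.
#' @param tail_ms silence appended after the last trial.
#' @return List with `recording` (a [recording()]) and `ground_truth`
#'   (designed gains, per-channel true HGA ratios computed from the gains by
#'   the same clipped-ratio formula as the estimator, latent factors, seed).
#' @export
synthesize_recording <- function(specs, trials, stimuli, common_noise_sd = 0,
                                 line_hz = NULL, seed = 1,
                                 acoustic_latent = NULL, carrier_amp = 1,
                                 tail_ms = 4000) {
  stopifnot(length(specs) >= 1)
  dur <- stimuli$duration_ms[1]
  set.seed(seed)
  n <- max(trials$onset_sample) + dur + tail_ms
  nch <- length(specs)
  volt <- matrix(0, nrow = nch, ncol = n)
  common <- if (common_noise_sd > 0) common_noise_sd * onef_noise(n) else 0
  line <- if (!is.null(line_hz)) sin(2 * pi * line_hz * seq_len(n) / 1000) else 0
  bf <- signal::butter(3, c(70, 150) / 500, type = "pass")
  vocal <- stimuli$vocal[match(trials$stimulus_id, stimuli$stimulus_id)]
  for (ch in seq_len(nch)) {
    sp <- specs[[ch]]
    carrier <- signal::filtfilt(bf, stats::rnorm(n))
    carrier <- carrier / stats::sd(carrier)
    env <- rep(1, n)
    for (i in seq_len(nrow(trials))) {
      g_on <- if (vocal[i]) sp$onset_gain_v else sp$onset_gain_nv
      g_sus <- if (vocal[i]) sp$sustained_gain_v else sp$sustained_gain_nv
      if (!is.null(sp$acoustic_weights) && !is.null(acoustic_latent)) {
        shift <- sum(sp$acoustic_weights *
          acoustic_latent[trials$stimulus_id[i], ])
        g_on <- max(0, g_on + shift)
        g_sus <- max(0, g_sus + shift)
      }
      if (g_on == 0 && g_sus == 0) next
      start <- trials$onset_sample[i] + round(sp$latency_ms) + 1
      prof <- trial_gain_profile(g_on, g_sus, dur)
      idx <- start:(start + dur - 1)
      ok <- idx >= 1 & idx <= n
      env[idx[ok]] <- env[idx[ok]] + prof[ok]
    }
    volt[ch, ] <- sp$noise_sd * onef_noise(n) + common + line +
      carrier_amp * env * carrier
  }
  chans <- channel_info(sprintf("sim_%02d", seq_len(nch)),
    roi = "other", hemisphere = "left"
  )
  gt_ratio <- data.frame(
    channel_id = chans$channel_id,
    role = vapply(specs, function(s) s$role, character(1)),
    ratio_onset = vapply(
      specs,
      function(s) hga_ratio(s$onset_gain_v, s$onset_gain_nv), numeric(1)
    ),
    ratio_sustained = vapply(
      specs,
      function(s) hga_ratio(s$sustained_gain_v, s$sustained_gain_nv),
      numeric(1)
    ),
    stringsAsFactors = FALSE
  )
  list(
    recording = recording(volt, 1000, chans),
    ground_truth = list(
      specs = specs, true_ratio = gt_ratio,
      acoustic_latent = acoustic_latent, seed = seed,
      carrier_amp = carrier_amp, common_noise_sd = common_noise_sd
    )
  )
}

#' Synthetic acoustic feature table with low-rank latent structure
#'
#' Features are generated as `latent %*% loadings + noise`, with latent
#' factor means shifted between the vocal and nonvocal categories by
#' `category_shift`, so category membership is partially (not fully)
#' linearly recoverable from the acoustics — emulating the confound between
#' category and acoustics in natural sound sets. The default feature count
#' (88) mirrors the size of standard acoustic "functionals" summaries.
#'
#' @param stimuli a [stimulus_table()].
#' @param n_features number of observed feature columns.
#' @param n_latent number of latent factors (`<= n_features`).
#' @param category_shift numeric vector (recycled to `n_latent`) giving the
#'   vocal-minus-nonvocal latent mean difference.
#' @param noise_sd SD of the added feature noise.
#' @param seed random seed.
#' @return List with `features` (stimuli x n_features matrix, rows named by
#'   stimulus id), `latent` (stimuli x n_latent score matrix), `loadings`.
#' @export
make_acoustic_features <- function(stimuli, n_features = 88, n_latent = 5,
                                   category_shift = 0, noise_sd = 0.1,
                                   seed = 1) {
  if (n_latent < 1) stop("n_latent must be >= 1")
  if (n_latent > n_features) stop("n_latent must not exceed n_features")
  set.seed(seed)
  ns <- nrow(stimuli)
  shift <- rep_len(category_shift, n_latent)
  latent <- matrix(stats::rnorm(ns * n_latent), ns, n_latent)
  latent <- latent + outer(ifelse(stimuli$vocal, 0.5, -0.5), shift)
  rownames(latent) <- stimuli$stimulus_id
  loadings <- matrix(stats::rnorm(n_latent * n_features), n_latent, n_features)
  feats <- latent %*% loadings
  if (noise_sd > 0) {
    feats <- feats + matrix(stats::rnorm(ns * n_features, sd = noise_sd),
      ns, n_features
    )
  }
  rownames(feats) <- stimuli$stimulus_id
  colnames(feats) <- sprintf("feat_%02d", seq_len(n_features))
  list(features = feats, latent = latent, loadings = loadings)
}
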