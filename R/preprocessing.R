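#' Common average reference
#'
#' Subtracts the instantaneous across-channel mean from every channel,
#' removing noise common to all channels. After CAR the across-channel mean
#' is zero at every sample; the operation is idempotent.
#'
#' @param rec a [recording()] with at least 2 channels.
#' @return The re-referenced recording.
#' @export
apply_car <- function(rec) {
  stopifnot(inherits(rec, "vg_recording"))
  if (nrow(rec$voltage) < 2) {
    stop("common average reference needs >= 2 channels")
  }
  rec$voltage <- sweep(rec$voltage, 2, colMeans(rec$voltage))
  rec
}

#' Epoch a recording around stimulus onsets
#'
#' Extracts one voltage epoch per trial, from `epoch_pre_ms` before stimulus
#' onset to `epoch_post_offset_ms[task]` after stimulus offset (half-open in
#' ms: a VL trial spans `[-1000, 2000)` ms around onset for a 550-ms
#' stimulus, a NatS trial `[-1000, 3000)` for a 2000-ms stimulus).
#'
#' @param rec a [recording()] at 1 kHz.
#' @param trials a [trial_table()].
#' @param stimuli the matching [stimulus_table()].
#' @param cfg a [voice_config()].
#' @return Object of class `vg_epochs`: trials x channels x time array plus
#'   the 1-kHz time axis in ms relative to onset.
#' @export
epoch_voltage <- function(rec, trials, stimuli, cfg = voice_config()) {
  stopifnot(inherits(rec, "vg_recording"))
  fs <- rec$sample_rate_hz
  task <- stimuli$task[1]
  dur <- stimuli$duration_ms[1]
  start_ms <- -cfg$epoch_pre_ms
  end_ms <- dur + task_post_offset_ms(cfg, task)
  spm <- fs / 1000 # samples per ms
  n_time <- as.integer((end_ms - start_ms) * spm)
  if (!all(trials$stimulus_id %in% stimuli$stimulus_id)) {
    stop("trial table references unknown stimuli")
  }
  # 0-based onset o covers R indices o + 1 + [start_ms*spm, end_ms*spm)
  first <- trials$onset_sample + 1 + as.integer(start_ms * spm)
  last <- first + n_time - 1
  bad <- first < 1 | last > ncol(rec$voltage)
  if (any(bad)) {
    stop(
      "epoch out of recording bounds for trial id(s): ",
      paste(trials$trial_id[bad], collapse = ", ")
    )
  }
  nc <- nrow(rec$voltage)
  data <- array(0, dim = c(nrow(trials), nc, n_time))
  for (i in seq_len(nrow(trials))) {
    data[i, , ] <- rec$voltage[, first[i]:last[i]]
  }
  structure(
    list(
      data = data,
      time_ms = seq(start_ms, end_ms - 1 / spm, by = 1 / spm),
      sample_rate_hz = fs, task = task, duration_ms = dur,
      trials = trials, channels = rec$channels, normalized = FALSE
    ),
    class = "vg_epochs"
  )
}

#' Normalize epochs to the prestimulus period
#'
#' Per channel, mean and SD are computed over the pooled prestimulus samples
#' of all trials, and the full epochs are z-transformed with those pooled
#' statistics. Scale-invariant: rescaling the input voltage leaves the output
#' unchanged.
#'
#' @param ep a `vg_epochs` object.
#' @param cfg a [voice_config()].
#' @return The normalized `vg_epochs`.
#' @export
normalize_epochs <- function(ep, cfg = voice_config()) {
  stopifnot(inherits(ep, "vg_epochs"))
  pre <- which(ep$time_ms < 0)
  if (!length(pre)) stop("no prestimulus span in epochs")
  for (ch in seq_len(dim(ep$data)[2])) {
    base <- ep$data[, ch, pre]
    m <- mean(base)
    s <- stats::sd(as.vector(base))
    if (!is.finite(s) || s == 0) {
      stop("degenerate channel (zero prestimulus variance): ",
        ep$channels$channel_id[ch])
    }
    ep$data[, ch, ] <- (ep$data[, ch, ] - m) / s
  }
  ep$normalized <- TRUE
  ep
}

#' High-gamma filter bank definition
#'
#' Eight Butterworth bandpass filters with center frequencies log-spaced from
#' 70 to 150 Hz and bandwidths log-spaced from 16 to 64 Hz; band `i` spans
#' `center +- bandwidth/2`.
#'
#' @param cfg a [voice_config()].
#' @param sample_rate_hz sampling rate the bank will be applied at, used to
#'   validate band edges against the Nyquist frequency.
#' @return data.frame with `center_hz`, `bandwidth_hz`, `low_hz`, `high_hz`,
#'   `order`.
#' @export
make_filter_bank <- function(cfg = voice_config(), sample_rate_hz = 1000) {
  n <- cfg$n_bands
  if (n < 2) stop("n_bands must be >= 2")
  ctr <- cfg$hga_band_hz[1] *
    (cfg$hga_band_hz[2] / cfg$hga_band_hz[1])^(seq(0, n - 1) / (n - 1))
  bw <- cfg$bandwidth_range_hz[1] *
    (cfg$bandwidth_range_hz[2] / cfg$bandwidth_range_hz[1])^(seq(0, n - 1) / (n - 1))
  lo <- ctr - bw / 2
  hi <- ctr + bw / 2
  if (any(hi >= sample_rate_hz / 2)) {
    stop("filter band edge at or above Nyquist frequency")
  }
  if (any(lo <= 0)) stop("filter band edge at or below 0 Hz")
  data.frame(
    center_hz = ctr, bandwidth_hz = bw, low_hz = lo, high_hz = hi,
    order = cfg$filter_order
  )
}

# Analytic-signal amplitude (Hilbert envelope) of a real vector, via the
# standard one-sided spectrum construction. No installed R package exposes
# this primitive.
analytic_amplitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Extract broadband high-gamma activity
#'
#' For each filter-bank band, the epochs are forward-and-reverse filtered
#' (zero phase), the analytic amplitude is taken via the Hilbert transform,
#' and the amplitude is z-normalized against a pooled baseline across all
#' trials. The baseline excludes the earliest 100 ms of the prestimulus span
#' (filter edge effects) and the 100 ms immediately preceding onset
#' (low-latency responses). HGA is the mean across the normalized bands,
#' down-sampled to 100 Hz by averaging consecutive non-overlapping 10-ms
#' bins, and clipped to bins starting within `[-900, offset + 900]` ms.
#'
#' @param ep a normalized `vg_epochs` at 1 kHz.
#' @param cfg a [voice_config()].
#' @return Object of class `vg_hga`: trials x channels x time array at
#'   100 Hz (baseline-z units), with `time_ms` giving 10-ms bin starts.
#' @export
extract_hga <- function(ep, cfg = voice_config()) {
  stopifnot(inherits(ep, "vg_epochs"))
  fs <- ep$sample_rate_hz
  bank <- make_filter_bank(cfg, fs)
  nt <- dim(ep$data)[1]
  nc <- dim(ep$data)[2]
  ns <- dim(ep$data)[3]
  min_len <- 4 * 3 * cfg$filter_order # filtfilt warm-up margin
  if (ns < min_len) stop("epoch shorter than filter warm-up")
  edge <- cfg$baseline_edge_discard_ms
  base_idx <- which(ep$time_ms >= ep$time_ms[1] + edge & ep$time_ms < -edge)
  hga <- array(0, dim = c(nt, nc, ns))
  for (b in seq_len(nrow(bank))) {
    # filter_order is the bandpass order; signal::butter doubles the
    # prototype order for type = "pass"
    bf <- signal::butter(cfg$filter_order / 2,
      c(bank$low_hz[b], bank$high_hz[b]) / (fs / 2),
      type = "pass"
    )
    amp <- array(0, dim = c(nt, nc, ns))
    for (ch in seq_len(nc)) {
      for (tr in seq_len(nt)) {
        amp[tr, ch, ] <- analytic_amplitude(
          signal::filtfilt(bf, ep$data[tr, ch, ])
        )
      }
    }
    if (cfg$band_norm_pool_channels) {
      m <- mean(amp[, , base_idx])
      s <- stats::sd(as.vector(amp[, , base_idx]))
      amp <- (amp - m) / s
    } else {
      for (ch in seq_len(nc)) {
        base <- amp[, ch, base_idx]
        m <- mean(base)
        s <- stats::sd(as.vector(base))
        if (!is.finite(s) || s == 0) {
          stop("degenerate band amplitude in channel ",
            ep$channels$channel_id[ch])
        }
        amp[, ch, ] <- (amp[, ch, ] - m) / s
      }
    }
    hga <- hga + amp / nrow(bank)
  }
  # downsample by mean over consecutive non-overlapping bins
  dec <- as.integer(fs / cfg$hga_rate_hz)
  nb <- ns %/% dec
  binner <- matrix(0, nrow = nb * dec, ncol = nb)
  binner[cbind(seq_len(nb * dec), rep(seq_len(nb), each = dec))] <- 1 / dec
  out <- array(0, dim = c(nt, nc, nb))
  for (ch in seq_len(nc)) {
    out[, ch, ] <- matrix(hga[, ch, seq_len(nb * dec)], nrow = nt) %*% binner
  }
  bin_start_ms <- ep$time_ms[seq(1, nb * dec, by = dec)]
  keep <- bin_start_ms >= -cfg$clip_pre_ms &
    bin_start_ms <= ep$duration_ms + cfg$clip_post_offset_ms
  structure(
    list(
      data = out[, , keep, drop = FALSE],
      time_ms = bin_start_ms[keep],
      rate_hz = cfg$hga_rate_hz, task = ep$task,
      duration_ms = ep$duration_ms,
      trials = ep$trials, channels = ep$channels, bands = bank
    ),
    class = "vg_hga"
  )
}

#' Average single-trial HGA into stimulus responses
#'
#' Averages the HGA of all presentations of each stimulus, yielding one
#' response per stimulus (the unit of all stimulus-level analyses).
#'
#' @param hga a `vg_hga` object.
#' @param trials the trial table (defaults to the one carried by `hga`).
#' @param stimuli the stimulus table defining row order of the output.
#' @return Object of class `vg_stim_response`: stimuli x channels x time
#'   array plus per-stimulus presentation counts.
#' @export
average_stimulus_responses <- function(hga, trials = hga$trials, stimuli) {
  stopifnot(inherits(hga, "vg_hga"))
  if (!all(trials$stimulus_id %in% stimuli$stimulus_id)) {
    stop("trial table references stimuli missing from the stimulus table")
  }
  counts <- table(factor(trials$stimulus_id, levels = stimuli$stimulus_id))
  if (any(counts == 0)) {
    stop(
      "stimulus with zero presentations: ",
      paste(stimuli$stimulus_id[counts == 0], collapse = ", ")
    )
  }
  ns <- nrow(stimuli)
  nc <- dim(hga$data)[2]
  nt <- dim(hga$data)[3]
  out <- array(0, dim = c(ns, nc, nt))
  for (i in seq_len(ns)) {
    rows <- which(trials$stimulus_id == stimuli$stimulus_id[i])
    if (length(rows) == 1) {
      out[i, , ] <- hga$data[rows, , ]
    } else {
      out[i, , ] <- apply(hga$data[rows, , , drop = FALSE], c(2, 3), mean)
    }
  }
  structure(
    list(
      data = out, time_ms = hga$time_ms, rate_hz = hga$rate_hz,
      task = hga$task, duration_ms = hga$duration_ms,
      stimuli = stimuli, channels = hga$channels,
      n_presentations = as.integer(counts)
    ),
    class = "vg_stim_response"
  )
}
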