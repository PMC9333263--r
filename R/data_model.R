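#' Channel metadata table
#'
#' Builds and validates the per-channel metadata used throughout the
#' pipeline. Regions of interest (ROIs) follow the auditory hierarchy
#' vocabulary: Heschl's gyrus (HG) and planum temporale (PT) form the
#' supratemporal plane (STP); superior temporal gyrus (STG) and sulcus (STS)
#' form the STG/STS super-ROI. Channels labelled `other` are carried through
#' preprocessing but excluded from ROI contrasts.
#'
#' @param channel_id character vector of unique channel identifiers.
#' @param roi one of `"HG"`, `"PT"`, `"STG"`, `"STS"`, `"other"` per channel.
#' @param hemisphere `"left"` or `"right"` per channel.
#' @param dist_to_cortex_mm nonnegative distance from channel centroid to the
#'   nearest cortical vertex, in mm.
#'
#' @return A `data.frame` with the four columns above plus a derived
#'   `super_roi` column (`"STP"`, `"STG/STS"`, or `"other"`).
#' @export
channel_info <- function(channel_id, roi, hemisphere = "left",
                         dist_to_cortex_mm = 0) {
  channel_id <- as.character(channel_id)
  n <- length(channel_id)
  if (anyDuplicated(channel_id)) stop("channel_id values must be unique")
  roi <- rep_len(as.character(roi), n)
  hemisphere <- rep_len(as.character(hemisphere), n)
  dist_to_cortex_mm <- rep_len(as.numeric(dist_to_cortex_mm), n)
  if (!all(roi %in% c("HG", "PT", "STG", "STS", "other"))) {
    stop("roi must be one of HG, PT, STG, STS, other")
  }
  if (!all(hemisphere %in% c("left", "right"))) {
    stop("hemisphere must be 'left' or 'right'")
  }
  if (any(!is.finite(dist_to_cortex_mm)) || any(dist_to_cortex_mm < 0)) {
    stop("dist_to_cortex_mm must be finite and >= 0")
  }
  data.frame(
    channel_id = channel_id, roi = roi, hemisphere = hemisphere,
    dist_to_cortex_mm = dist_to_cortex_mm,
    super_roi = super_roi(roi),
    stringsAsFactors = FALSE
  )
}

#' Map an ROI label to its super-ROI
#'
#' HG and PT map to STP; STG and STS map to STG/STS; `other` stays `other`.
#' The mapping is total and deterministic.
#'
#' @param roi character vector of ROI labels.
#' @return character vector of super-ROI labels.
#' @export
super_roi <- function(roi) {
  out <- ifelse(roi %in% c("HG", "PT"), "STP",
    ifelse(roi %in% c("STG", "STS"), "STG/STS",
      ifelse(roi == "other", "other", NA_character_)
    )
  )
  if (anyNA(out)) stop("unknown roi label(s): ", paste(unique(roi[is.na(out)]), collapse = ", "))
  out
}

#' Multichannel voltage recording
#'
#' @param voltage channels x samples numeric matrix (microvolts).
#' @param sample_rate_hz positive sampling rate (the recordings this package
#'   targets are sampled at 1 kHz).
#' @param channels channel metadata as returned by [channel_info()]; its row
#'   count must equal `nrow(voltage)`.
#'
#' @return An object of class `vg_recording`.
#' @export
recording <- function(voltage, sample_rate_hz, channels) {
  voltage <- as.matrix(voltage)
  if (!is.numeric(voltage)) stop("voltage must be numeric")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
    sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a positive scalar")
  }
  if (!is.data.frame(channels) || is.null(channels$channel_id)) {
    stop("channels must be a channel_info data.frame")
  }
  if (nrow(voltage) != nrow(channels)) {
    stop(
      "voltage has ", nrow(voltage), " rows but channel table has ",
      nrow(channels), " rows"
    )
  }
  rownames(voltage) <- channels$channel_id
  structure(
    list(
      voltage = voltage, sample_rate_hz = as.numeric(sample_rate_hz),
      channels = channels
    ),
    class = "vg_recording"
  )
}

#' @export
print.vg_recording <- function(x, ...) {
  cat(
    "<vg_recording> ", nrow(x$voltage), " channels x ", ncol(x$voltage),
    " samples @ ", x$sample_rate_hz, " Hz\n",
    sep = ""
  )
  invisible(x)
}

#' Stimulus metadata table
#'
#' @param stimulus_id unique stimulus identifiers.
#' @param task `"VL"` (voice localizer) or `"NatS"` (natural sounds); must be
#'   constant within a table.
#' @param category stimulus category label.
#' @param vocal logical: does the stimulus contain a (human) vocalization?
#' @param speech logical: does it contain speech? Speech implies vocal.
#' @param duration_ms positive stimulus duration, constant within task
#'   (550 ms for VL, 2000 ms for NatS by design).
#' @param excluded_from_encoding logical: drop from encoding models (e.g.
#'   acoustic-feature outliers).
#'
#' @return A validated `data.frame`.
#' @export
stimulus_table <- function(stimulus_id, task, category, vocal, speech = FALSE,
                           duration_ms = NULL,
                           excluded_from_encoding = FALSE) {
  stimulus_id <- as.character(stimulus_id)
  n <- length(stimulus_id)
  if (anyDuplicated(stimulus_id)) stop("stimulus_id values must be unique")
  task <- rep_len(as.character(task), n)
  if (!all(task %in% c("VL", "NatS"))) stop("task must be 'VL' or 'NatS'")
  if (length(unique(task)) > 1) stop("task must be constant within a table")
  if (is.null(duration_ms)) duration_ms <- if (task[1] == "VL") 550 else 2000
  duration_ms <- rep_len(as.numeric(duration_ms), n)
  if (any(duration_ms <= 0)) stop("duration_ms must be positive")
  if (length(unique(duration_ms)) > 1) {
    stop("duration_ms must be constant within a task")
  }
  vocal <- rep_len(as.logical(vocal), n)
  speech <- rep_len(as.logical(speech), n)
  if (any(speech & !vocal)) stop("speech stimuli must be flagged vocal")
  data.frame(
    stimulus_id = stimulus_id, task = task,
    category = rep_len(as.character(category), n),
    vocal = vocal, speech = speech, duration_ms = duration_ms,
    excluded_from_encoding = rep_len(as.logical(excluded_from_encoding), n),
    stringsAsFactors = FALSE
  )
}

#' Trial schedule table
#'
#' @param trial_id integer trial indices.
#' @param stimulus_id stimulus presented on each trial.
#' @param onset_sample 0-based onset sample index into the recording;
#'   must be strictly increasing.
#' @param is_repeat logical: immediate (1-back) repeat of the previous trial.
#' @param response_time_ms optional behavioral response times.
#'
#' @return A validated `data.frame`.
#' @export
trial_table <- function(trial_id, stimulus_id, onset_sample,
                        is_repeat = FALSE, response_time_ms = NA_real_) {
  n <- length(trial_id)
  onset_sample <- as.integer(onset_sample)
  if (n > 1 && any(diff(onset_sample) <= 0)) {
    stop("onset_sample must be strictly increasing")
  }
  if (any(onset_sample < 0)) stop("onset_sample must be >= 0 (0-based)")
  data.frame(
    trial_id = as.integer(trial_id),
    stimulus_id = as.character(stimulus_id),
    onset_sample = onset_sample,
    is_repeat = rep_len(as.logical(is_repeat), n),
    response_time_ms = rep_len(as.numeric(response_time_ms), n),
    stringsAsFactors = FALSE
  )
}

#' Balance voice-localizer classes
#'
#' The voice-localizer stimulus preparation keeps all vocal sounds and only
#' the first `min(n_nonvocal, n_vocal)` nonvocal sounds in their canonical
#' sequence, producing equal class counts.
#'
#' @param n_nonvocal number of nonvocal stimuli available.
#' @param n_vocal number of vocal stimuli available.
#' @param order character vector listing the nonvocal stimulus ids in their
#'   canonical sequence (length `n_nonvocal`).
#'
#' @return Character vector of retained nonvocal stimulus ids.
#' @export
balance_vl_classes <- function(n_nonvocal, n_vocal, order) {
  if (n_nonvocal < 0 || n_vocal < 0) stop("counts must be nonnegative")
  if (length(order) != n_nonvocal) {
    stop("order must list all ", n_nonvocal, " nonvocal stimuli")
  }
  keep <- min(n_nonvocal, n_vocal)
  as.character(order[seq_len(keep)])
}

#' Apply the class-balancing rule to a VL stimulus table
#'
#' Keeps all vocal rows and the first `n_vocal` nonvocal rows (table order is
#' the canonical sequence).
#'
#' @param stimuli a VL [stimulus_table()].
#' @return The balanced stimulus table.
#' @export
balance_vl_table <- function(stimuli) {
  nv_ids <- stimuli$stimulus_id[!stimuli$vocal]
  keep_nv <- balance_vl_classes(length(nv_ids), sum(stimuli$vocal), nv_ids)
  out <- stimuli[stimuli$vocal | stimuli$stimulus_id %in% keep_nv, ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  out
}

#' Reclassify natural-sound stimuli from vocal to nonvocal
#'
#' Moves the listed stimuli from the vocal to the nonvocal superordinate
#' category, as done for crowd-generated sounds and sounds without vocal-fold
#' vibration (e.g. breathing, whistling). All other rows are unchanged; the
#' total row count is preserved.
#'
#' @param table a [stimulus_table()].
#' @param reclassify_ids stimulus ids currently flagged vocal (and not
#'   speech) to be reclassified.
#'
#' @return The modified stimulus table.
#' @export
reclassify_nats_vocal <- function(table, reclassify_ids) {
  reclassify_ids <- as.character(reclassify_ids)
  if (!length(reclassify_ids)) return(table)
  idx <- match(reclassify_ids, table$stimulus_id)
  if (anyNA(idx)) {
    stop(
      "stimulus id(s) not found: ",
      paste(reclassify_ids[is.na(idx)], collapse = ", ")
    )
  }
  if (any(!table$vocal[idx])) {
    stop(
      "stimulus id(s) already nonvocal: ",
      paste(reclassify_ids[!table$vocal[idx]], collapse = ", ")
    )
  }
  if (any(table$speech[idx])) {
    stop("cannot reclassify speech stimuli to nonvocal")
  }
  table$vocal[idx] <- FALSE
  table
}

#' Summarize per-patient channel counts
#'
#' @param per_patient a data.frame with columns `responsive` and `total`, or
#'   a list of `(responsive, total)` pairs.
#'
#' @return A list with `sum_responsive`, `min`, and `max` (extrema over the
#'   per-patient responsive counts).
#' @export
summarize_channel_counts <- function(per_patient) {
  if (is.data.frame(per_patient)) {
    resp <- per_patient$responsive
    tot <- per_patient$total
  } else {
    resp <- vapply(per_patient, function(x) x[[1]], numeric(1))
    tot <- vapply(per_patient, function(x) x[[2]], numeric(1))
  }
  if (!length(resp)) stop("per_patient must be non-empty")
  if (any(resp < 0) || any(tot < 0)) stop("counts must be nonnegative")
  if (any(resp > tot)) {
    stop("responsive count exceeds total for patient(s) ", paste(which(resp > tot), collapse = ", "))
  }
  list(
    sum_responsive = as.integer(sum(resp)),
    min = as.integer(min(resp)),
    max = as.integer(max(resp))
  )
}
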