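#' Write a recording container
#'
#' Serializes a recording to a directory container holding the voltage array
#' as delimited text (`voltage.tsv`, samples x channels), the channel table
#' (`channels.tsv`), and a small JSON header (`meta.json`) with the sample
#' rate and array shape. Round-trips losslessly at full double precision.
#'
#' @param rec a [recording()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "vg_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "voicegate-recording",
    sample_rate_hz = rec$sample_rate_hz,
    n_channels = nrow(rec$voltage),
    n_samples = ncol(rec$voltage)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  utils::write.table(rec$channels[setdiff(names(rec$channels), "super_roi")],
    file.path(path, "channels.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  # samples x channels, full precision
  con <- file(file.path(path, "voltage.tsv"), "w")
  on.exit(close(con))
  writeLines(paste(rec$channels$channel_id, collapse = "\t"), con)
  utils::write.table(
    format(t(rec$voltage), digits = 17, trim = TRUE, scientific = TRUE),
    con,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a recording container
#'
#' @param path directory written by [write_recording()].
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  if (!dir.exists(path)) stop("no such container: ", path)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("container missing meta.json: ", path)
  meta <- jsonlite::read_json(meta_path)
  for (f in c("sample_rate_hz", "n_channels", "n_samples")) {
    if (is.null(meta[[f]])) stop("meta.json missing field: ", f)
  }
  chan_path <- file.path(path, "channels.tsv")
  if (!file.exists(chan_path)) stop("container missing channel table: ", path)
  ch <- utils::read.table(chan_path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, colClasses = c(channel_id = "character")
  )
  channels <- channel_info(
    ch$channel_id, ch$roi, ch$hemisphere,
    ch$dist_to_cortex_mm
  )
  v <- as.matrix(utils::read.table(file.path(path, "voltage.tsv"),
    header = TRUE, sep = "\t", check.names = FALSE
  ))
  if (ncol(v) != meta$n_channels || nrow(v) != meta$n_samples) {
    stop(
      "voltage array is ", nrow(v), "x", ncol(v),
      " but meta.json declares ", meta$n_samples, "x", meta$n_channels
    )
  }
  if (nrow(channels) != ncol(v)) {
    stop("channel table rows do not match voltage columns")
  }
  recording(t(v), meta$sample_rate_hz, channels)
}

#' Read/write trial and stimulus tables
#'
#' Trial and stimulus tables are stored as UTF-8 tab-delimited text with a
#' header row.
#'
#' @param x table to write.
#' @param path file path.
#' @return The table (readers) or `path` invisibly (writers).
#' @export
write_trial_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  d <- utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = c(stimulus_id = "character")
  )
  trial_table(
    d$trial_id, d$stimulus_id, d$onset_sample, d$is_repeat,
    if (is.null(d$response_time_ms)) NA_real_ else d$response_time_ms
  )
}

#' @rdname write_trial_table
#' @export
write_stimulus_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_stimulus_table <- function(path) {
  d <- utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = c(stimulus_id = "character")
  )
  stimulus_table(
    d$stimulus_id, d$task, d$category, d$vocal, d$speech,
    d$duration_ms,
    if (is.null(d$excluded_from_encoding)) FALSE else d$excluded_from_encoding
  )
}
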