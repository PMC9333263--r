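# In-memory fixtures shared across tests. Statistical stages are exercised
# on arrays built directly in the package's container layout, so they can be
# tested without running the signal chain each time.

nats_time_grid <- function() seq(-900, 2900, by = 10)

fake_hga <- function(data, time_ms, trials, task = "NatS",
                     duration_ms = 2000, channels = NULL) {
  if (is.null(channels)) {
    channels <- channel_info(sprintf("ch%02d", seq_len(dim(data)[2])), "STG")
  }
  structure(
    list(
      data = data, time_ms = time_ms, rate_hz = 100, task = task,
      duration_ms = duration_ms, trials = trials, channels = channels,
      bands = NULL
    ),
    class = "vg_hga"
  )
}

fake_resp <- function(data, time_ms, stimuli, task = "NatS",
                      duration_ms = 2000, channels = NULL) {
  if (is.null(channels)) {
    channels <- channel_info(sprintf("ch%02d", seq_len(dim(data)[2])), "STG")
  }
  structure(
    list(
      data = data, time_ms = time_ms, rate_hz = 100, task = task,
      duration_ms = duration_ms, stimuli = stimuli, channels = channels,
      n_presentations = rep(1L, dim(data)[1])
    ),
    class = "vg_stim_response"
  )
}

# trial table with one presentation per stimulus, regular onsets
simple_trials <- function(stimuli, spacing = 4000, lead = 2000) {
  n <- nrow(stimuli)
  trial_table(seq_len(n), stimuli$stimulus_id, lead + spacing * (seq_len(n) - 1))
}
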