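#' Run the preprocessing chain
#'
#' Convenience wrapper: common average reference, epoching, prestimulus
#' normalization, and broadband HGA extraction.
#'
#' @param rec a [recording()].
#' @param trials a [trial_table()].
#' @param stimuli the matching [stimulus_table()].
#' @param cfg a [voice_config()].
#' @param car apply the common average reference first (skip for
#'   single-channel fixtures).
#' @return A `vg_hga` object.
#' @export
preprocess_recording <- function(rec, trials, stimuli, cfg = voice_config(),
                                 car = TRUE) {
  if (car) rec <- apply_car(rec)
  ep <- epoch_voltage(rec, trials, stimuli, cfg)
  ep <- normalize_epochs(ep, cfg)
  extract_hga(ep, cfg)
}
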