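# Closed-loop glue: a "simulated subject" couples the synthetic-EEG stream
# to the online decoder, choosing an imagery class each tick from the task
# state the way a trained participant would (head for the cued target,
# then idle inside the hover area to let the cursor settle).

#' Create a simulated closed-loop subject
#'
#' Couples a [mu_stream()] to a [decoder_init()] state.  The subject's
#' modulation strength is set by `params$erd_depth` / `params$ers_gain`.
#'
#' @param params a [sim_params()].
#' @param config a [decoder_config()]; its `update_interval` is the task
#'   engine tick.
#' @return a subject environment.
#' @export
bci_subject <- function(params = sim_params(), config = decoder_config()) {
  if (params$sampling_rate <= 2 * config$bandpass[2])
    stop_config("decoder bandpass incompatible with the simulated sampling rate")
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$config <- config
  st$stream <- mu_stream(params, "REST")
  st$decoder <- decoder_init(config, params$sampling_rate)
  st$tick_samples <- round(config$update_interval * params$sampling_rate)
  st
}

#' Warm up a subject's decoder on resting-state signal
#'
#' Streams REST signal through the decoder so the adaptive normalizer
#' settles at the baseline feature statistics before feedback begins.
#'
#' @param subject a [bci_subject()].
#' @param seconds warm-up duration.
#' @export
subject_warmup <- function(subject, seconds = 20) {
  n_ticks <- round(seconds / subject$config$update_interval)
  for (i in seq_len(n_ticks)) {
    blk <- stream_imagery(subject$stream, "REST", subject$tick_samples)
    decoder_step(subject$decoder, blk, update_norm = TRUE)
  }
  invisible(subject)
}

# Imagery choice of a trained subject: idle (REST) inside the hover disc of
# the cued target, otherwise imagery for the dominant axis of the error.
subject_imagery <- function(state, hover_radius, vertical = FALSE) {
  tgt <- c(state$layout$x[state$cued], state$layout$y[state$cued])
  err <- tgt - state$pos
  if (sqrt(sum(err^2)) <= hover_radius) return("REST")
  if (!vertical && abs(err[1]) >= abs(err[2])) {
    if (err[1] > 0) "RIGHT_HAND" else "LEFT_HAND"
  } else {
    if (err[2] > 0) "BOTH_HANDS" else "RELAX"
  }
}

#' Control source driven by a simulated subject
#'
#' Returns a per-tick control function for [run_trial()] /
#' [run_vertical_trial()]: each tick the subject picks an imagery class
#' from the task state, the stream emits one tick of EEG, and the decoder
#' turns it into a velocity command.
#'
#' @param subject a [bci_subject()].
#' @param task_cfg a [task_config()]; its `tick` must equal the decoder
#'   update interval.
#' @param vertical `TRUE` for the 1-D grasp/release steps (uses
#'   `grasp_tolerance` as the settle radius).
#' @param imagery fixed imagery class overriding the subject's strategy
#'   (e.g. `"REST"` for chance runs).
#' @return a control-source function.
#' @export
subject_control <- function(subject, task_cfg = task_config(),
                            vertical = FALSE, imagery = NULL) {
  if (abs(task_cfg$tick - subject$config$update_interval) > 1e-9)
    stop_config("task tick must equal the decoder update interval")
  radius <- if (vertical) task_cfg$grasp_tolerance else task_cfg$hover_radius
  function(state) {
    img <- if (is.null(imagery))
      subject_imagery(state, radius, vertical) else imagery
    blk <- stream_imagery(subject$stream, img, subject$tick_samples)
    cs <- decoder_step(subject$decoder, blk, update_norm = TRUE)
    if (length(cs) == 0) return(c(0, 0))
    last <- cs[[length(cs)]]
    c(last$vx, last$vy)
  }
}
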