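# Performance accounting: percent valid correct (PVC), time-to-hit,
# blocks-per-run, and Monte-Carlo chance-level estimation under a resting /
# random control policy.

result_outcomes <- function(results) {
  if (is.character(results)) return(results)
  if (inherits(results, "trial_result")) return(results$outcome)
  vapply(results, function(r)
    if (is.character(r)) r else r$outcome, character(1))
}

#' Percent valid correct
#'
#' `100 * n_hit / (n_hit + n_miss)`: the ratio of correct target hits to
#' all valid (hit or miss) outcomes.  Aborted/timed-out trials are invalid
#' and excluded.  Returns `NA` with attribute `undefined = TRUE` when no
#' valid trials exist.
#'
#' @param results character vector of outcomes, or a list of trial results.
#' @return PVC in percent.
#' @export
pvc <- function(results) {
  oc <- result_outcomes(results)
  n_hit <- sum(oc == "HIT")
  n_miss <- sum(oc == "MISS")
  if (n_hit + n_miss == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * n_hit / (n_hit + n_miss)
}

chance_layout <- function(stage) {
  switch(stage,
         cursor1d = layout_lr(),
         cursor2d = layout_fixed4(),
         cursor2d5 = layout_fixed5(),
         stop_arg(sprintf("unknown stage '%s'", stage)))
}

#' Monte-Carlo chance-level estimation
#'
#' Runs the virtual-cursor paradigm under an intent-free control policy —
#' either an i.i.d. zero-mean Gaussian random walk or the full decoder fed
#' a resting-state (REST) synthetic-EEG stream — with a uniformly random
#' cued target per trial, and reports the PVC with aborts excluded.
#' Paradigms "without hovering time" (`no_hover = TRUE`) declare selection
#' on the first disc entry.
#'
#' @param stage `"cursor1d"` (2 lateral targets), `"cursor2d"` (4 targets)
#'   or `"cursor2d5"` (4 + centre target).
#' @param n_trials number of simulated trials (>= 100 recommended).
#' @param seed integer seed.
#' @param config a [task_config()].
#' @param policy `"random_walk"` or `"decoder_rest"`.
#' @param sigma random-walk per-axis velocity SD, cm/s.  PVC is invariant
#'   to it on symmetric layouts; it only sets the valid-trial rate.
#' @param no_hover zero the hover dwell (selection on first entry).
#' @param params [sim_params()] for the `decoder_rest` policy.
#' @param dec_config [decoder_config()] for the `decoder_rest` policy.
#' @return list: `pvc`, counts, per-25-trial-run hit counts, a binomial
#'   95% CI on the PVC, and the outcome vector.
#' @export
chance_level <- function(stage = c("cursor1d", "cursor2d", "cursor2d5"),
                         n_trials = 2000, seed = 1L,
                         config = task_config(),
                         policy = c("random_walk", "decoder_rest"),
                         sigma = 20, no_hover = TRUE,
                         params = NULL, dec_config = NULL) {
  stage <- match.arg(stage)
  policy <- match.arg(policy)
  if (n_trials < 100)
    warning("fewer than 100 trials: high Monte-Carlo error")
  if (no_hover) config$hover_duration <- 0
  layout <- chance_layout(stage)
  axis <- if (stage == "cursor1d") "x" else NULL
  n_max <- as.integer(round(config$max_feedback / config$tick))

  subject <- NULL
  if (policy == "decoder_rest") {
    if (is.null(params))
      params <- sim_params(sampling_rate = 250, line_noise_amp = 0,
                           seed = substream_seed(seed, 7001L))
    if (is.null(dec_config))
      dec_config <- decoder_config(bandpass = c(0.5, 100),
                                   update_interval = config$tick)
    subject <- bci_subject(params, dec_config)
    subject_warmup(subject, 20)
  }

  outcomes <- character(n_trials)
  with_seed(seed, {
    cues <- sample.int(nrow(layout), n_trials, replace = TRUE)
    for (i in seq_len(n_trials)) {
      src <- if (policy == "random_walk")
        matrix(stats::rnorm(2 * n_max, 0, sigma), n_max, 2)
      else subject_control(subject, config, imagery = "REST")
      outcomes[i] <- run_trial(src, layout, cues[i], config,
                               axis = axis)$outcome
    }
  })
  n_hit <- sum(outcomes == "HIT")
  n_miss <- sum(outcomes == "MISS")
  n_valid <- n_hit + n_miss
  p <- pvc(outcomes)
  ci <- if (n_valid > 0)
    100 * stats::binom.test(n_hit, n_valid)$conf.int else c(NA_real_, NA_real_)
  runs <- split(outcomes, ceiling(seq_along(outcomes) / 25))
  list(stage = stage, policy = policy, pvc = as.numeric(p),
       n_hit = n_hit, n_miss = n_miss,
       n_abort = sum(outcomes == "ABORT"), n_valid = n_valid,
       ci = as.numeric(ci),
       hits_per_run = vapply(runs, function(r) sum(r == "HIT"), numeric(1)),
       outcomes = outcomes)
}

#' Summarise a run of trials and sequences
#'
#' @param results list of trial results (individual steps).
#' @param sequences optional list of sequence results; completed sequences
#'   count as grasped/moved blocks.
#' @param config a [task_config()] (phase overheads for the run duration).
#' @param block_cap optional cap on countable blocks per run (13 steps for
#'   the fixed-target grasp runs, 10 blocks for random targets, 6 moves for
#'   the shelf runs).
#' @return a `run_summary` list: counts, `pvc`, `mean_time_to_hit` (HIT
#'   trials), `blocks_completed`, `run_duration`.
#' @export
summarize_run <- function(results, sequences = NULL,
                          config = task_config(), block_cap = NULL) {
  oc <- result_outcomes(results)
  tth <- vapply(results, function(r)
    if (is.list(r)) r$time_to_hit else NA_real_, numeric(1))
  n_hit <- sum(oc == "HIT"); n_miss <- sum(oc == "MISS")
  blocks <- if (!is.null(sequences))
    sum(vapply(sequences, `[[`, logical(1), "completed")) else 0L
  if (!is.null(block_cap)) blocks <- min(blocks, block_cap)
  overhead <- config$iti + config$prefeedback + config$postfeedback
  structure(list(
    n_hit = n_hit, n_miss = n_miss, n_abort = sum(oc == "ABORT"),
    pvc = as.numeric(pvc(oc)),
    mean_time_to_hit = if (n_hit > 0) mean(tth[oc == "HIT"]) else NA_real_,
    blocks_completed = blocks,
    run_duration = sum(tth, na.rm = TRUE) + overhead * length(oc)),
    class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "<run_summary> HIT %d / MISS %d / ABORT %d | PVC %.1f%% | mean time-to-hit %.2f s | blocks %d | duration %.1f s\n",
    x$n_hit, x$n_miss, x$n_abort, x$pvc,
    if (is.na(x$mean_time_to_hit)) NA else x$mean_time_to_hit,
    x$blocks_completed, x$run_duration))
  invisible(x)
}
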