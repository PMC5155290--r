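# Synthetic-EEG "simulated subject": seeded multichannel signals with the
# task-locked mu-rhythm modulation structure the online decoder and the
# ERD/ERS analysis assume.  The mu rhythm is an amplitude-modulated
# narrowband oscillator (random phase, slow frequency jitter) over C3 and
# C4; Laplacian-neighbour channels carry an attenuated copy of the nearest
# source plus independent background, and all channels share a common
# broadband component (the part a spatial high-pass rejects), so the small
# Laplacian has spatial structure to exploit.

DEFAULT_MONTAGE <- c("C3", "FC3", "CP3", "C1", "C5",
                     "C4", "FC4", "CP4", "C2", "C6")

DEFAULT_LAPLACIAN_MAP <- list(
  C3 = c("FC3", "CP3", "C1", "C5"),
  C4 = c("FC4", "CP4", "C2", "C6"))

#' Simulation parameters for the synthetic-EEG generator
#'
#' @param sampling_rate sampling rate in Hz. 1000 Hz is the nominal
#'   acquisition rate; tests and demos may scale it down.
#' @param channel_labels montage labels; must include C3, C4 and each one's
#'   four small-Laplacian neighbours.
#' @param mu_center_freq mu oscillator centre frequency, Hz.
#' @param mu_baseline_amp baseline mu amplitude at the source, uV (peak).
#' @param erd_depth fractional mu-amplitude attenuation during ERD, in
#'   `[0, 1)`: the active-period source amplitude is `(1 - erd_depth)` times
#'   baseline, so band power scales by `(1 - erd_depth)^2`.
#' @param ers_gain fractional mu-amplitude increase during ERS (>= 0).
#' @param background_exponent spectral slope beta of the 1/f^beta background.
#' @param background_sigma RMS of the channel-independent broadband
#'   background, uV.
#' @param common_sigma RMS of the spatially common (shared across all
#'   channels) broadband background, uV.  This is the component a spatial
#'   high-pass such as the small Laplacian rejects; without it a Laplacian
#'   derivation could never beat the raw channel.
#' @param line_noise_amp amplitude of the 60 Hz mains component, uV.
#' @param modulation_latency seconds from cue to full modulation (linear
#'   ramp).
#' @param leakage fraction of the nearest mu source mixed into each
#'   Laplacian-neighbour channel.
#' @param freq_jitter_sd standard deviation of the slow mu frequency jitter,
#'   Hz.
#' @param seed root RNG seed; together with the other fields it fully
#'   determines every generated sample.
#' @return a `sim_params` list.
#' @export
sim_params <- function(sampling_rate = 1000,
                       channel_labels = DEFAULT_MONTAGE,
                       mu_center_freq = 12,
                       mu_baseline_amp = 20,
                       erd_depth = 0.5,
                       ers_gain = 0.2,
                       background_exponent = 1,
                       background_sigma = 5,
                       common_sigma = 15,
                       line_noise_amp = 1,
                       modulation_latency = 0.5,
                       leakage = 0.5,
                       freq_jitter_sd = 0.3,
                       seed = 1L) {
  check_scalar(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_scalar(erd_depth, "erd_depth", lower = 0)
  if (erd_depth >= 1) stop_arg("`erd_depth` must be < 1")
  check_scalar(ers_gain, "ers_gain", lower = 0)
  check_scalar(mu_baseline_amp, "mu_baseline_amp", lower = 0)
  check_scalar(background_sigma, "background_sigma", lower = 0)
  check_scalar(common_sigma, "common_sigma", lower = 0)
  check_scalar(line_noise_amp, "line_noise_amp", lower = 0)
  check_scalar(modulation_latency, "modulation_latency", lower = 0)
  check_scalar(leakage, "leakage", lower = 0)
  top <- max(mu_center_freq + 5 * freq_jitter_sd,
             if (line_noise_amp > 0) 60 else 0)
  if (sampling_rate <= 2 * top)
    stop_arg(sprintf(
      "sampling_rate (%g Hz) must exceed twice the highest generated frequency (%g Hz); drop the 60 Hz line component or raise the rate",
      sampling_rate, top))
  need <- c("C3", "C4", unlist(DEFAULT_LAPLACIAN_MAP))
  miss <- setdiff(need, channel_labels)
  if (length(miss))
    stop_arg(paste("channel_labels must include C3/C4 and their Laplacian",
                   "neighbours; missing:", paste(miss, collapse = ", ")))
  structure(list(
    sampling_rate = sampling_rate, channel_labels = channel_labels,
    mu_center_freq = mu_center_freq, mu_baseline_amp = mu_baseline_amp,
    erd_depth = erd_depth, ers_gain = ers_gain,
    background_exponent = background_exponent,
    background_sigma = background_sigma, common_sigma = common_sigma,
    line_noise_amp = line_noise_amp,
    modulation_latency = modulation_latency, leakage = leakage,
    freq_jitter_sd = freq_jitter_sd, seed = as.integer(seed)),
    class = "sim_params")
}

#' Default trial-phase timing
#'
#' Inter-trial interval, prefeedback (target display), feedback (control)
#' and postfeedback durations in seconds.  The cursor paradigm displays the
#' target for 3 s before feedback; the robot paradigm for 2.5 s.
#'
#' @param iti,prefeedback,feedback,postfeedback phase durations in seconds.
#' @return a named list of durations.
#' @export
trial_timing <- function(iti = 2, prefeedback = 3, feedback = 4,
                         postfeedback = 1) {
  tm <- list(iti = iti, prefeedback = prefeedback, feedback = feedback,
             postfeedback = postfeedback)
  for (nm in names(tm)) check_scalar(tm[[nm]], nm, lower = 0)
  tm
}

#' Hemispheric mu-amplitude modulation factors per imagery class
#'
#' Returns the multiplicative factors applied to the C3 (left-hemisphere)
#' and C4 (right-hemisphere) mu sources: right-hand imagery attenuates the
#' contralateral (left) hemisphere, left-hand the right hemisphere,
#' both-hands both, and relaxation increases both (ERS).  REST leaves both
#' at baseline.
#'
#' @param imagery one of [IMAGERY_CLASSES].
#' @param params a [sim_params()] object.
#' @return named numeric vector `c(left = , right = )`.
#' @export
class_modulation <- function(imagery, params) {
  imagery <- match.arg(imagery, IMAGERY_CLASSES)
  d <- params$erd_depth
  g <- params$ers_gain
  switch(imagery,
         RIGHT_HAND = c(left = 1 - d, right = 1),
         LEFT_HAND  = c(left = 1,     right = 1 - d),
         BOTH_HANDS = c(left = 1 - d, right = 1 - d),
         RELAX      = c(left = 1 + g, right = 1 + g),
         REST       = c(left = 1,     right = 1))
}

# One mu oscillator realisation: amplitude 1, centre frequency f0 with slow
# AR(1) jitter, random initial phase.  Draws consume the current RNG stream.
mu_oscillator <- function(n, fs, f0, jitter_sd) {
  phi0 <- stats::runif(1, 0, 2 * pi)
  if (jitter_sd > 0) {
    rho <- exp(-1 / (0.2 * fs))  # ~200 ms jitter correlation time
    innov_sd <- jitter_sd * sqrt(1 - rho^2)
    j <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                                  method = "recursive"))
  } else {
    j <- numeric(n)
  }
  phase <- phi0 + 2 * pi * cumsum(f0 + j) / fs
  sin(phase)
}

background_matrix <- function(n, params) {
  fs <- params$sampling_rate
  nch <- length(params$channel_labels)
  out <- matrix(0, nch, n)
  tt <- (0:(n - 1)) / fs
  common <- shaped_noise(n, fs, params$background_exponent,
                         params$common_sigma)
  if (params$line_noise_amp > 0) {
    ph <- stats::runif(1, 0, 2 * pi)   # mains is common across the montage
    common <- common + params$line_noise_amp * sin(2 * pi * 60 * tt + ph)
  }
  for (i in seq_len(nch))
    out[i, ] <- common + shaped_noise(n, fs, params$background_exponent,
                                      params$background_sigma)
  out
}

#' Generate task-free background EEG
#'
#' 1/f-shaped Gaussian noise per channel plus a 60 Hz mains sinusoid of
#' amplitude `line_noise_amp`.  Fully determined by `params$seed`.
#'
#' @param duration seconds (> 0).
#' @param params a [sim_params()] object.
#' @return an [eeg_recording()].
#' @export
generate_background <- function(duration, params) {
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  n <- round(duration * params$sampling_rate)
  dat <- with_seed(params$seed, background_matrix(n, params))
  eeg_recording(dat, params$sampling_rate, params$channel_labels)
}

# Piecewise-linear modulation envelope for one trial: baseline 1 until the
# cue (prefeedback onset), linear ramp to `factor` over `modulation_latency`,
# held until feedback end, then a ramp back to baseline.
modulation_envelope <- function(n, fs, factor, pre_onset, fb_end, latency) {
  tt <- (0:(n - 1)) / fs
  env <- rep(1, n)
  if (latency > 0) {
    up <- tt >= pre_onset & tt < pre_onset + latency
    env[up] <- 1 + (factor - 1) * (tt[up] - pre_onset) / latency
    hold <- tt >= pre_onset + latency & tt < fb_end
    env[hold] <- factor
    down <- tt >= fb_end & tt < fb_end + latency
    env[down] <- factor + (1 - factor) * (tt[down] - fb_end) / latency
  } else {
    env[tt >= pre_onset & tt < fb_end] <- factor
  }
  env
}

#' Generate one task trial of synthetic EEG
#'
#' Mu bursts at C3/C4 are scaled by the [class_modulation()] factors from
#' cue (prefeedback onset) plus `modulation_latency` until feedback end;
#' background noise is added everywhere; each Laplacian-neighbour channel
#' receives `leakage` times the nearest source plus independent background.
#'
#' @param imagery one of [IMAGERY_CLASSES].
#' @param timing a [trial_timing()] list.
#' @param params a [sim_params()] object.
#' @param trial_index counter used to derive the per-trial RNG substream.
#' @param t0 trial start time in seconds (event timestamps are offset by it).
#' @return list with elements `recording` ([eeg_recording()]) and `events`
#'   (one-row [trial_events()] table).
#' @export
generate_trial <- function(imagery, timing = trial_timing(), params,
                           trial_index = 1L, t0 = 0) {
  imagery <- match.arg(imagery, IMAGERY_CLASSES)
  fs <- params$sampling_rate
  durs <- unlist(timing[c("iti", "prefeedback", "feedback", "postfeedback")])
  if (any(durs < 0)) stop_arg("phase durations must be >= 0")
  nper <- round(durs * fs)
  n <- sum(nper)
  pre_onset <- nper[["iti"]] / fs
  fb_onset <- (nper[["iti"]] + nper[["prefeedback"]]) / fs
  fb_end <- fb_onset + nper[["feedback"]] / fs
  post_end <- n / fs

  fac <- class_modulation(imagery, params)
  dat <- with_seed(substream_seed(params$seed, trial_index), {
    bg <- background_matrix(n, params)
    src_l <- params$mu_baseline_amp *
      modulation_envelope(n, fs, fac[["left"]], pre_onset, fb_end,
                          params$modulation_latency) *
      mu_oscillator(n, fs, params$mu_center_freq, params$freq_jitter_sd)
    src_r <- params$mu_baseline_amp *
      modulation_envelope(n, fs, fac[["right"]], pre_onset, fb_end,
                          params$modulation_latency) *
      mu_oscillator(n, fs, params$mu_center_freq, params$freq_jitter_sd)
    add_sources(bg, params$channel_labels, src_l, src_r, params$leakage)
  })
  rec <- eeg_recording(dat, fs, params$channel_labels, start_time = t0)
  ev <- data.frame(trial_index = trial_index, target_class = imagery,
                   iti_onset = t0, prefeedback_onset = t0 + pre_onset,
                   feedback_onset = t0 + fb_onset,
                   feedback_end = t0 + fb_end, post_end = t0 + post_end,
                   outcome = NA_character_, stringsAsFactors = FALSE)
  list(recording = rec, events = trial_events(ev))
}

add_sources <- function(bg, labels, src_l, src_r, leakage) {
  add <- function(lab, sig) {
    i <- match(lab, labels)
    if (!is.na(i)) bg[i, ] <<- bg[i, ] + sig
  }
  add("C3", src_l)
  add("C4", src_r)
  for (lab in DEFAULT_LAPLACIAN_MAP$C3) add(lab, leakage * src_l)
  for (lab in DEFAULT_LAPLACIAN_MAP$C4) add(lab, leakage * src_r)
  bg
}

#' Generate a full session from a trial plan
#'
#' @param trial_plan either a character vector of imagery classes (each trial
#'   using `timing`) or a list of `list(imagery =, timing =)` entries.
#' @param params a [sim_params()] object.
#' @param timing default [trial_timing()] for plain character plans.
#' @return list with `recording` and `events` covering all trials, with
#'   event timestamps aligned to the sample grid.
#' @export
generate_session <- function(trial_plan, params, timing = trial_timing()) {
  if (length(trial_plan) == 0) stop_arg("trial plan must be non-empty")
  if (is.character(trial_plan))
    trial_plan <- lapply(trial_plan, function(cl)
      list(imagery = cl, timing = timing))
  recs <- vector("list", length(trial_plan))
  evs <- vector("list", length(trial_plan))
  t0 <- 0
  for (k in seq_along(trial_plan)) {
    tr <- generate_trial(trial_plan[[k]]$imagery, trial_plan[[k]]$timing,
                         params, trial_index = k, t0 = t0)
    recs[[k]] <- tr$recording
    evs[[k]] <- tr$events
    t0 <- t0 + rec_duration(tr$recording)
  }
  list(recording = concat_recordings(recs),
       events = trial_events(do.call(rbind, evs)))
}
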