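# Core containers: multichannel EEG recordings and trial event tables.

#' Imagery class vocabulary
#'
#' The five motor-imagery conditions driving the control scheme: unilateral
#' hand imagery (contralateral mu ERD), both-hands imagery (bilateral ERD),
#' relaxation (bilateral ERS) and REST (no task; baseline runs).
#'
#' @export
IMAGERY_CLASSES <- c("LEFT_HAND", "RIGHT_HAND", "BOTH_HANDS", "RELAX", "REST")

#' Construct an EEG recording
#'
#' A thin container for a channels-by-samples signal matrix in microvolts,
#' with channel labels, sampling rate and a start time.
#'
#' @param data numeric matrix, channels x samples, in uV.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`.
#' @param start_time recording start time in seconds.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels,
                          start_time = 0) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_arg("`data` must be a numeric matrix (channels x samples)")
  if (length(channel_labels) != nrow(data))
    stop_validation("channel label count must equal the number of data rows")
  check_scalar(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  if (anyNA(data))
    stop_validation("recording data must not contain NA/NaN values")
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         start_time = start_time),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param x an `eeg_recording`.
#' @return number of samples (`n_samples`) or duration in seconds.
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname n_samples
#' @export
rec_duration <- function(x) ncol(x$data) / x$sampling_rate

#' Extract one channel as a numeric vector
#' @param x an `eeg_recording`.
#' @param label channel label.
#' @return numeric vector of samples (uV).
#' @export
get_channel <- function(x, label) {
  i <- match(label, x$channel_labels)
  if (is.na(i))
    stop_channel(sprintf("channel '%s' not found (available: %s)", label,
                         paste(x$channel_labels, collapse = ", ")))
  x$data[i, ]
}

#' Concatenate recordings along time
#' @param ... `eeg_recording` objects with identical channels and rates.
#' @return a single `eeg_recording`.
#' @export
concat_recordings <- function(...) {
  recs <- list(...)
  if (length(recs) == 1L && is.list(recs[[1]]) &&
      !inherits(recs[[1]], "eeg_recording")) recs <- recs[[1]]
  r1 <- recs[[1]]
  for (r in recs[-1]) {
    if (!identical(r$channel_labels, r1$channel_labels) ||
        r$sampling_rate != r1$sampling_rate)
      stop_validation("recordings must share channels and sampling rate")
  }
  eeg_recording(do.call(cbind, lapply(recs, function(r) r$data)),
                r1$sampling_rate, r1$channel_labels, r1$start_time)
}

#' Construct / validate a trial event table
#'
#' One row per trial with the four phase timestamps (inter-trial interval,
#' prefeedback, feedback onset, feedback end), the cued imagery class, the
#' post-feedback end time and the scored outcome (`NA` before scoring).
#'
#' @param df data.frame with columns `trial_index`, `target_class`,
#'   `iti_onset`, `prefeedback_onset`, `feedback_onset`, `feedback_end`,
#'   `post_end`, `outcome`.
#' @return a validated `trial_events` data.frame.
#' @export
trial_events <- function(df) {
  needed <- c("trial_index", "target_class", "iti_onset", "prefeedback_onset",
              "feedback_onset", "feedback_end", "post_end", "outcome")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop_validation(paste("missing event columns:",
                          paste(miss, collapse = ", ")))
  bad <- setdiff(unique(df$target_class), IMAGERY_CLASSES)
  if (length(bad))
    stop_validation(sprintf(
      "unknown imagery label(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(IMAGERY_CLASSES, collapse = ", ")))
  df <- df[order(df$iti_onset), , drop = FALSE]
  within_ok <- with(df, iti_onset <= prefeedback_onset &
                      prefeedback_onset < feedback_onset &
                      feedback_onset < feedback_end &
                      feedback_end <= post_end)
  if (!all(within_ok))
    stop_validation("trial phase timestamps must be increasing within trials")
  if (nrow(df) > 1L) {
    if (any(df$iti_onset[-1L] < df$post_end[-nrow(df)] - 1e-9))
      stop_validation("trials must not overlap")
  }
  rownames(df) <- NULL
  class(df) <- c("trial_events", "data.frame")
  df
}
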