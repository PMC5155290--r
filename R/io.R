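# Format readers/writers.  Signals: EDF (European Data Format, 16-bit) as
# the binary interchange format, or (optionally gzip-compressed) delimited
# text as the exact-round-trip debug format.  Events: tab-separated tables
# with onset/duration/trial_index/label columns.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to EDF
#'
#' Minimal EDF writer: 16-bit samples, physical unit uV, one-second data
#' records (the tail is zero-padded to a whole record).  Quantization error
#' is bounded by one digital step of each channel's physical range.
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop_io("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  dat <- recording$data
  ns <- nrow(dat)
  n <- ncol(dat)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n)
    dat <- cbind(dat, matrix(0, ns, n_rec * fs - n))
  pmin_ <- apply(dat, 1, min)
  pmax_ <- apply(dat, 1, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field(sprintf("Startdate 01-JAN-2000 mubci n=%d", n), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  fld <- function(vals, w) paste0(vapply(vals, pad_field, "", width = w),
                                  collapse = "")
  hdr <- paste0(hdr,
    fld(recording$channel_labels, 16), fld(rep("", ns), 80),
    fld(rep("uV", ns), 8),
    fld(sprintf("%.8g", pmin_), 8), fld(sprintf("%.8g", pmax_), 8),
    fld(rep("-32768", ns), 8), fld(rep("32767", ns), 8),
    fld(rep("", ns), 80), fld(rep(fs, ns), 8), fld(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  scale <- 65535 / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((dat[i, idx] - pmin_[i]) * scale[i] - 32768))
      writeBin(pmin(pmax(dig, -32768L), 32767L), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file written by [write_edf()] or any plain (non EDF+)
#'   EDF file with a uniform per-signal rate.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1L)
    stop_io("mixed per-signal rates are not supported")
  fs <- spr[1] / rec_dur
  dat <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      dat[i, idx] <- (dig - dmin_[i]) / (dmax_[i] - dmin_[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
    }
  }
  eeg_recording(dat, fs, labels)
}

#' Read / write recordings by extension
#'
#' `.edf` dispatches to the EDF reader/writer; `.tsv` / `.tsv.gz` use a
#' delimited text layout (one column per channel, `#`-prefixed metadata
#' lines for sampling rate and start time) with exact float round-trip.
#'
#' @param recording an [eeg_recording()].
#' @param path file path; the extension selects the format.
#' @return `read_recording()` returns an [eeg_recording()].
#' @export
write_recording <- function(recording, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    return(write_edf(recording, path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate=%.17g", recording$sampling_rate),
               sprintf("# start_time=%.17g", recording$start_time),
               paste(recording$channel_labels, collapse = "\t")), con)
  utils::write.table(
    format(t(recording$data), digits = 17, scientific = TRUE, trim = TRUE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    return(read_edf(path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(paste0("^# *", key, "="), meta, value = TRUE)
    if (length(m) == 0) return(default)
    as.numeric(sub(paste0("^# *", key, "="), "", m[1]))
  }
  fs <- get_meta("sampling_rate", NA)
  if (is.na(fs)) stop_io("missing '# sampling_rate=' metadata line")
  t0 <- get_meta("start_time", 0)
  body <- lines[!grepl("^#", lines)]
  labels <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  ncols <- lengths(rows)
  bad <- which(ncols != length(labels))
  if (length(bad))
    stop_io(sprintf(
      "line %d has %d column(s) but the header names %d channel(s)",
      bad[1] + length(meta) + 1L, ncols[bad[1]], length(labels)))
  dat <- t(vapply(rows, as.numeric, numeric(length(labels))))
  if (anyNA(dat)) stop_io("non-numeric value in signal body")
  eeg_recording(t(dat), fs, labels, start_time = t0)
}

#' Write / read trial events as tab-separated text
#'
#' File layout: columns `onset`, `duration`, `trial_index`, `label`; each
#' trial contributes one row per phase (inter-trial interval, prefeedback,
#' feedback, postfeedback, in that order), all labelled with the trial's
#' imagery class.
#'
#' @param events a [trial_events()] table.
#' @param path TSV path.
#' @return `read_events()` returns a validated [trial_events()] table.
#' @export
write_events <- function(events, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    on <- c(e$iti_onset, e$prefeedback_onset, e$feedback_onset,
            e$feedback_end)
    dur <- c(e$prefeedback_onset - e$iti_onset,
             e$feedback_onset - e$prefeedback_onset,
             e$feedback_end - e$feedback_onset,
             e$post_end - e$feedback_end)
    data.frame(onset = on, duration = dur, trial_index = e$trial_index,
               label = e$target_class, stringsAsFactors = FALSE)
  }))
  utils::write.table(format(rows, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_index", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_io(paste("missing event columns:", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(df$label), IMAGERY_CLASSES)
  if (length(bad))
    stop_validation(sprintf("label(s) %s not in the imagery vocabulary (%s)",
                            paste(bad, collapse = ", "),
                            paste(IMAGERY_CLASSES, collapse = ", ")))
  df <- df[order(df$trial_index, df$onset), , drop = FALSE]
  out <- do.call(rbind, lapply(split(df, df$trial_index), function(g) {
    if (nrow(g) != 4L)
      stop_validation(sprintf("trial %d has %d phase rows (expected 4)",
                              g$trial_index[1], nrow(g)))
    data.frame(trial_index = g$trial_index[1], target_class = g$label[1],
               iti_onset = g$onset[1], prefeedback_onset = g$onset[2],
               feedback_onset = g$onset[3], feedback_end = g$onset[4],
               post_end = g$onset[4] + g$duration[4],
               outcome = NA_character_, stringsAsFactors = FALSE)
  }))
  trial_events(out)
}

# --- run configuration ---------------------------------------------------

#' Full run configuration
#'
#' Nested sections mirroring the simulation, decoder, task and ERD
#' parameter sets, plus a global seed and an output directory.  Unknown
#' keys are rejected; the file form (JSON) round-trips losslessly.
#'
#' @param simulation,decoder,task,erd parameter lists (see [sim_params()],
#'   [decoder_config()], [task_config()], [erd_params()]).
#' @param seed global seed.
#' @param output_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = sim_params(),
                       decoder = decoder_config(),
                       task = task_config(),
                       erd = erd_params(),
                       seed = 1L, output_dir = ".") {
  structure(list(simulation = simulation, decoder = decoder, task = task,
                 erd = erd, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

config_section <- function(values, constructor, name) {
  defaults <- formals(constructor)
  allowed <- names(defaults)
  unknown <- setdiff(names(values), allowed)
  if (length(unknown))
    stop_validation(sprintf("unknown key(s) in section '%s': %s", name,
                            paste(unknown, collapse = ", ")))
  do.call(constructor, values)
}

#' Read / write a run configuration (JSON)
#'
#' @param config a [run_config()].
#' @param path JSON path.
#' @return `read_run_config()` returns a validated [run_config()].
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.function, logical(1))]
  }
  out <- list(simulation = strip(config$simulation),
              decoder = strip(config$decoder),
              task = strip(config$task),
              erd = strip(config$erd),
              seed = config$seed, output_dir = config$output_dir)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  top_allowed <- c("simulation", "decoder", "task", "erd", "seed",
                   "output_dir")
  unknown <- setdiff(names(raw), top_allowed)
  if (length(unknown))
    stop_validation(paste("unknown top-level key(s):",
                          paste(unknown, collapse = ", ")))
  # drop derived fields that the constructors recompute
  sim <- raw$simulation
  dec <- raw$decoder
  tsk <- raw$task
  # stored durations are already in effective (possibly fast-scaled) form
  tsk <- tsk[setdiff(names(tsk), "fast")]
  erd <- raw$erd
  if (!is.null(dec$laplacian_map))
    dec$laplacian_map <- lapply(dec$laplacian_map, unlist)
  task_cfg <- config_section(tsk, task_config, "task")
  if (isTRUE(raw$task$fast)) task_cfg$fast <- TRUE
  run_config(
    simulation = config_section(sim, sim_params, "simulation"),
    decoder = config_section(dec, decoder_config, "decoder"),
    task = task_cfg,
    erd = config_section(erd, erd_params, "erd"),
    seed = if (is.null(raw$seed)) 1L else raw$seed,
    output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir)
}
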