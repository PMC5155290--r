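# Online control pipeline: zero-phase conditioning (0.5-200 Hz bandpass +
# 60 Hz notch), small-Laplacian spatial filtering at C3/C4, sliding-window
# least-squares autoregressive (AR) spectral estimation of the upper-mu
# (10-14 Hz) amplitude, adaptive exponentially-weighted normalization, and
# a linear mapping of the two hemispheric features to a 2-axis velocity
# command.

#' Decoder configuration
#'
#' @param band_low,band_high upper-mu control band edges, Hz.
#' @param ar_order AR model order (least-squares / covariance method).
#' @param window_length sliding analysis window, seconds.
#' @param update_interval control update period, seconds (one velocity
#'   command per interval).
#' @param laplacian_map named list: centre channel -> its four neighbours.
#' @param gain_x,gain_y velocity gains, cm/s per normalized feature unit.
#' @param normalizer_halflife half-life of the adaptive feature normalizer,
#'   seconds.
#' @param notch_freq mains notch frequency, Hz.
#' @param bandpass length-2 conditioning passband, Hz.
#' @param spectrum_spacing frequency grid spacing used when averaging the AR
#'   amplitude across the band, Hz.
#' @return a `decoder_config` list.
#' @export
decoder_config <- function(band_low = 10, band_high = 14, ar_order = 16,
                           window_length = 0.4, update_interval = 0.04,
                           laplacian_map = DEFAULT_LAPLACIAN_MAP,
                           gain_x = 5, gain_y = 5,
                           normalizer_halflife = 20,
                           notch_freq = 60, bandpass = c(0.5, 200),
                           spectrum_spacing = 1) {
  if (band_low >= band_high) stop_config("band_low must be < band_high")
  if (update_interval > window_length)
    stop_config("update_interval must be <= window_length")
  check_scalar(ar_order, "ar_order", lower = 1)
  check_scalar(normalizer_halflife, "normalizer_halflife", lower = 0,
               strict_lower = TRUE)
  structure(list(
    band_low = band_low, band_high = band_high, ar_order = as.integer(ar_order),
    window_length = window_length, update_interval = update_interval,
    laplacian_map = laplacian_map, gain_x = gain_x, gain_y = gain_y,
    normalizer_halflife = normalizer_halflife, notch_freq = notch_freq,
    bandpass = bandpass, spectrum_spacing = spectrum_spacing),
    class = "decoder_config")
}

#' Condition a recording (bandpass + mains notch, zero phase)
#'
#' @param recording an [eeg_recording()].
#' @param config a [decoder_config()].
#' @return the filtered recording (same length and channels).
#' @export
condition <- function(recording, config = decoder_config()) {
  fs <- recording$sampling_rate
  if (fs <= 2 * config$bandpass[2])
    stop_config(sprintf(
      "sampling rate %g Hz too low for a %g Hz bandpass edge", fs,
      config$bandpass[2]))
  if (config$ar_order >= config$window_length * fs)
    stop_config("ar_order must be below window_length * sampling_rate")
  dat <- recording$data
  for (i in seq_len(nrow(dat)))
    dat[i, ] <- fft_filter(dat[i, ], fs, lo = config$bandpass[1],
                           hi = config$bandpass[2],
                           notch = config$notch_freq)
  eeg_recording(dat, fs, recording$channel_labels, recording$start_time)
}

#' Small-Laplacian spatial filter
#'
#' Returns the centre channel minus the mean of its four mapped neighbours,
#' sample-wise.
#'
#' @param recording an [eeg_recording()].
#' @param center centre channel label (e.g. "C3").
#' @param config a [decoder_config()] providing `laplacian_map`.
#' @return numeric vector (uV).
#' @export
small_laplacian <- function(recording, center, config = decoder_config()) {
  nb <- config$laplacian_map[[center]]
  if (is.null(nb))
    stop_channel(sprintf("no Laplacian neighbour map for channel '%s'",
                         center))
  ctr <- get_channel(recording, center)
  nbm <- vapply(nb, function(l) get_channel(recording, l),
                numeric(n_samples(recording)))
  ctr - rowMeans(nbm)
}

#' Least-squares (covariance method) AR model fit
#'
#' Fits `y_t = sum_i w_i y_(t-i) + e_t` by minimising the squared one-step
#' prediction error over the window (normal equations with a small ridge for
#' conditioning; this is the covariance/least-squares formulation, not
#' Yule-Walker).  A constant window is flagged degenerate and returns zero
#' coefficients.
#'
#' @param window numeric sample vector (length > order).
#' @param order AR order p.
#' @return an `ar_model` list: `coefficients`, `order`, `residual_variance`,
#'   `degenerate`.
#' @export
fit_ar <- function(window, order) {
  order <- as.integer(order)
  n <- length(window)
  if (n < order + 1L)
    stop_arg("window must be longer than the AR order")
  if (stats::sd(window) == 0)
    return(structure(list(coefficients = numeric(order), order = order,
                          residual_variance = 0, degenerate = TRUE),
                     class = "ar_model"))
  y <- window[(order + 1L):n]
  X <- matrix(0, n - order, order)
  for (i in seq_len(order)) X[, i] <- window[(order + 1L - i):(n - i)]
  XtX <- crossprod(X)
  ridge <- 1e-8 * mean(diag(XtX))
  w <- tryCatch(
    solve(XtX + diag(ridge, order), crossprod(X, y)),
    error = function(e) NULL)
  if (is.null(w))
    return(structure(list(coefficients = numeric(order), order = order,
                          residual_variance = stats::var(window),
                          degenerate = TRUE),
                     class = "ar_model"))
  res <- y - X %*% w
  structure(list(coefficients = as.numeric(w), order = order,
                 residual_variance = mean(res^2), degenerate = FALSE),
            class = "ar_model")
}

#' AR transfer-function amplitude spectrum
#'
#' Evaluates `sqrt(residual_variance) / |1 - sum_i w_i exp(-i 2 pi f i/fs)|`
#' on a frequency grid.
#'
#' @param model an `ar_model`.
#' @param freqs frequencies, Hz.
#' @param sampling_rate Hz.
#' @return amplitude at each frequency.
#' @export
ar_amplitude_spectrum <- function(model, freqs, sampling_rate) {
  w <- model$coefficients
  k <- seq_along(w)
  amp <- vapply(freqs, function(f) {
    A <- 1 - sum(w * exp(-1i * 2 * pi * f * k / sampling_rate))
    sqrt(model$residual_variance) / Mod(A)
  }, numeric(1))
  amp
}

#' Mean AR band amplitude
#'
#' Mean of the AR amplitude spectrum over a fixed grid of bins spanning the
#' band (default 1 Hz spacing).
#'
#' @param model an `ar_model`.
#' @param band length-2 band, Hz, within `(0, sampling_rate/2)`.
#' @param sampling_rate Hz.
#' @param spacing grid spacing, Hz.
#' @return band amplitude (uV).
#' @export
ar_band_amplitude <- function(model, band, sampling_rate, spacing = 1) {
  if (length(band) != 2L || band[1] >= band[2] || band[1] <= 0 ||
      band[2] >= sampling_rate / 2)
    stop_arg("band must lie within (0, sampling_rate/2)")
  grid <- seq(band[1], band[2], by = spacing)
  mean(ar_amplitude_spectrum(model, grid, sampling_rate))
}

#' Adaptive feature normalizer (exponentially weighted z-score)
#'
#' The linear power-to-velocity mapping needs a zero-mean control signal;
#' the normalizer tracks an exponentially-weighted mean and variance of the
#' raw band amplitude with the configured half-life, updating only while
#' feedback is active.
#'
#' @param halflife half-life in seconds.
#' @param update_interval decoder update period in seconds.
#' @return a normalizer-state environment.
#' @export
norm_state <- function(halflife, update_interval) {
  st <- new.env(parent = emptyenv())
  st$lambda <- 2^(-update_interval / halflife)
  st$m <- 0; st$v <- 0; st$n <- 0L
  st
}

#' Normalize one raw feature value
#'
#' @param state a [norm_state()] environment (modified in place when
#'   `update` is `TRUE`).
#' @param x raw feature value.
#' @param update whether to update the running statistics (feedback periods
#'   only).
#' @return z-value; `0` (flagged via attribute `degenerate`) while the
#'   running variance is zero.
#' @export
normalize_feature <- function(state, x, update = TRUE) {
  if (update) {
    if (state$n == 0L) {
      state$m <- x; state$v <- 0
    } else {
      lam <- state$lambda
      d <- x - state$m
      state$m <- state$m + (1 - lam) * d
      state$v <- lam * (state$v + (1 - lam) * d^2)
    }
    state$n <- state$n + 1L
  }
  if (state$v <= 0) {
    z <- 0
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (x - state$m) / sqrt(state$v)
}

#' Map the two hemispheric z-features to a velocity command
#'
#' `vx = gain_x * (right_z - left_z)`: right-hand imagery desynchronizes the
#' left hemisphere (C3, `left_z < 0`) and drives the cursor rightward.
#' `vy = gain_y * (-(left_z + right_z)/2)`: bilateral ERD (both-hands
#' imagery) drives upward, bilateral ERS (relaxation) downward.
#'
#' @param left_z,right_z normalized C3 / C4 band features.
#' @param config a [decoder_config()] (gains).
#' @return named numeric `c(vx =, vy =)` in cm/s.
#' @export
control_signal <- function(left_z, right_z, config = decoder_config()) {
  if (!is.finite(left_z) || !is.finite(right_z))
    stop_arg("control inputs must be finite")
  c(vx = config$gain_x * (right_z - left_z),
    vy = config$gain_y * (-(left_z + right_z) / 2))
}

#' Initialise online decoder state
#'
#' @param config a [decoder_config()].
#' @param sampling_rate input sampling rate, Hz.
#' @return a decoder-state environment for [decoder_step()].
#' @export
decoder_init <- function(config, sampling_rate) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$fs <- sampling_rate
  st$win_n <- round(config$window_length * sampling_rate)
  st$step_n <- round(config$update_interval * sampling_rate)
  if (config$ar_order >= st$win_n)
    stop_config("ar_order must be below window_length * sampling_rate")
  st$buffer <- NULL          # raw channels x samples
  st$pending <- 0L           # samples since last emitted update
  st$norm_l <- norm_state(config$normalizer_halflife, config$update_interval)
  st$norm_r <- norm_state(config$normalizer_halflife, config$update_interval)
  st$t <- 0
  st$last <- NULL
  st
}

decoder_features <- function(st, lap_l, lap_r) {
  cfg <- st$config
  band <- c(cfg$band_low, cfg$band_high)
  ml <- fit_ar(lap_l, cfg$ar_order)
  mr <- fit_ar(lap_r, cfg$ar_order)
  c(left = ar_band_amplitude(ml, band, st$fs, cfg$spectrum_spacing),
    right = ar_band_amplitude(mr, band, st$fs, cfg$spectrum_spacing))
}

#' Feed a raw block to the online decoder
#'
#' Buffers the block, and for every elapsed `update_interval` with at least
#' `window_length` of signal available runs conditioning, small Laplacian at
#' C3/C4, AR fit, band-amplitude extraction, normalization and the velocity
#' mapping.  During warm-up (buffer underrun) the previous control state is
#' repeated with `warmup = TRUE`.
#'
#' @param state a [decoder_init()] environment (modified in place).
#' @param block an [eeg_recording()] block (raw, unconditioned).
#' @param update_norm whether the normalizer statistics are updated
#'   (feedback periods).
#' @return list of control states emitted for this block; each has
#'   `timestamp`, `left_feature`, `right_feature`, `left_z`, `right_z`,
#'   `vx`, `vy`, `warmup`.
#' @export
decoder_step <- function(state, block, update_norm = TRUE) {
  cfg <- state$config
  state$buffer <- if (is.null(state$buffer)) block$data
                  else cbind(state$buffer, block$data)
  keep <- max(2L * state$win_n, state$win_n + state$step_n)
  nbuf <- ncol(state$buffer)
  state$pending <- state$pending + ncol(block$data)
  out <- list()
  while (state$pending >= state$step_n) {
    state$pending <- state$pending - state$step_n
    state$t <- state$t + cfg$update_interval
    avail <- nbuf - state$pending
    if (avail < state$win_n) {            # warm-up: repeat last state
      cs <- state$last
      if (is.null(cs))
        cs <- list(timestamp = state$t, left_feature = NA_real_,
                   right_feature = NA_real_, left_z = 0, right_z = 0,
                   vx = 0, vy = 0, warmup = TRUE)
      cs$timestamp <- state$t; cs$warmup <- TRUE
      out[[length(out) + 1L]] <- cs
      next
    }
    seg_idx <- (avail - state$win_n + 1L):avail
    seg <- eeg_recording(state$buffer[, seg_idx, drop = FALSE], state$fs,
                         rownames(state$buffer))
    segc <- condition(seg, cfg)
    lap_l <- small_laplacian(segc, "C3", cfg)
    lap_r <- small_laplacian(segc, "C4", cfg)
    feats <- decoder_features(state, lap_l, lap_r)
    lz <- as.numeric(normalize_feature(state$norm_l, feats[["left"]],
                                       update = update_norm))
    rz <- as.numeric(normalize_feature(state$norm_r, feats[["right"]],
                                       update = update_norm))
    v <- control_signal(lz, rz, cfg)
    cs <- list(timestamp = state$t, left_feature = feats[["left"]],
               right_feature = feats[["right"]], left_z = lz, right_z = rz,
               vx = v[["vx"]], vy = v[["vy"]], warmup = FALSE)
    state$last <- cs
    out[[length(out) + 1L]] <- cs
  }
  if (nbuf > keep + state$pending) {
    drop_n <- nbuf - (keep + state$pending)
    state$buffer <- state$buffer[, -(seq_len(drop_n)), drop = FALSE]
  }
  out
}

#' Decode a whole recording offline
#'
#' Conditions the recording once, then emits one control state per
#' `update_interval` from sliding `window_length` windows; equivalent to the
#' streaming path but faster for stored sessions.
#'
#' @param recording an [eeg_recording()].
#' @param config a [decoder_config()].
#' @param update_norm logical vector (recycled) marking updates during which
#'   the normalizer adapts, e.g. feedback periods.
#' @return data.frame log: `timestamp`, `left_feature`, `right_feature`,
#'   `left_z`, `right_z`, `vx`, `vy`.
#' @export
decode_recording <- function(recording, config = decoder_config(),
                             update_norm = TRUE) {
  fs <- recording$sampling_rate
  rc <- condition(recording, config)
  lap_l <- small_laplacian(rc, "C3", config)
  lap_r <- small_laplacian(rc, "C4", config)
  win_n <- round(config$window_length * fs)
  step_n <- round(config$update_interval * fs)
  ends <- seq(win_n, n_samples(recording), by = step_n)
  update_norm <- rep_len(update_norm, length(ends))
  nl <- norm_state(config$normalizer_halflife, config$update_interval)
  nr <- norm_state(config$normalizer_halflife, config$update_interval)
  band <- c(config$band_low, config$band_high)
  res <- matrix(NA_real_, length(ends), 7)
  for (j in seq_along(ends)) {
    idx <- (ends[j] - win_n + 1L):ends[j]
    ml <- fit_ar(lap_l[idx], config$ar_order)
    mr <- fit_ar(lap_r[idx], config$ar_order)
    fl <- ar_band_amplitude(ml, band, fs, config$spectrum_spacing)
    fr <- ar_band_amplitude(mr, band, fs, config$spectrum_spacing)
    lz <- as.numeric(normalize_feature(nl, fl, update = update_norm[j]))
    rz <- as.numeric(normalize_feature(nr, fr, update = update_norm[j]))
    v <- control_signal(lz, rz, config)
    res[j, ] <- c(ends[j] / fs, fl, fr, lz, rz, v[["vx"]], v[["vy"]])
  }
  out <- as.data.frame(res)
  names(out) <- c("timestamp", "left_feature", "right_feature", "left_z",
                  "right_z", "vx", "vy")
  out
}
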