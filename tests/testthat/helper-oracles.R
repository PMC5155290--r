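# Independent oracles and small fixtures.  These deliberately re-implement
# the arithmetic under test in the most literal way possible (explicit
# loops, stats::lm, direct FFT masks) so that package results can be
# checked against a second, independent derivation.

# Small montage / low rate parameters for fast tests (no 60 Hz component,
# so the rate can stay low).
quick_params <- function(..., sampling_rate = 160, line_noise_amp = 0,
                         seed = 1L) {
  sim_params(sampling_rate = sampling_rate, line_noise_amp = line_noise_amp,
             seed = seed, ...)
}

quick_decoder <- function(...) {
  decoder_config(bandpass = c(0.5, 70), ...)
}

# Band power by direct FFT masking (written independently of the package's
# brick_bandpass): variance of the band-limited component.
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  X <- stats::fft(x)
  X[!(f >= lo & f <= hi)] <- 0
  xb <- Re(stats::fft(X, inverse = TRUE)) / n
  mean(xb^2)
}

# One-sided periodogram, power per bin.
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n^2
  k <- seq_len(floor(n / 2))
  list(freq = (k - 1) * fs / n, power = 2 * P[k])
}

# Brute-force trial-averaged power course: filter -> segment -> detrend
# (stats::lm) -> square -> centred moving average (explicit loop) ->
# decimate -> average.  Mirrors the documented pipeline with none of the
# package's vectorised shortcuts.
oracle_power_course <- function(x, fs, centers, window, bin,
                                detrend = "linear", smooth_dur = 0.1,
                                downsample = 0.05) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  X <- stats::fft(x)
  X[!(f >= bin[1] & f <= bin[2])] <- 0
  xf <- Re(stats::fft(X, inverse = TRUE)) / n

  rel <- round(window[1] * fs):round(window[2] * fs)
  w <- round(smooth_dur * fs)
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  ds <- max(1, round(downsample * fs))
  keep <- seq(1, length(rel), by = ds)
  courses <- NULL
  for (ci in centers) {
    idx <- round(ci * fs) + 1 + rel
    seg <- xf[idx]
    if (detrend == "linear") {
      tt <- seq_along(seg)
      seg <- as.numeric(stats::residuals(stats::lm(seg ~ tt)))
    } else if (detrend == "constant") {
      seg <- seg - mean(seg)
    }
    sq <- seg^2
    sm <- numeric(length(sq))
    for (j in seq_along(sq)) {
      lo <- max(1, j - half)
      hi <- min(length(sq), j + half)
      sm[j] <- mean(sq[lo:hi])
    }
    courses <- rbind(courses, sm[keep])
  }
  list(time = rel[keep] / fs, power = colMeans(courses),
       per_trial = courses)
}

# Simulate a stable AR(p) series driven by unit-variance Gaussian noise.
oracle_ar_series <- function(coefs, n, burn = 500) {
  e <- stats::rnorm(n + burn)
  x <- as.numeric(stats::filter(e, coefs, method = "recursive"))
  x[(burn + 1):(burn + n)]
}

# A straight-line control source: constant velocity towards a fixed point.
const_velocity <- function(vx, vy, n) {
  matrix(rep(c(vx, vy), each = n), n, 2)
}
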