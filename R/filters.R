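# Zero-phase FFT filtering.  Two flavours are used deliberately:
#  * `fft_filter()` with raised-cosine transition bands for the online
#    conditioning chain (benign edge behaviour on windows);
#  * `brick_bandpass()`, an exact rectangular frequency mask, for the offline
#    ERD pipeline, whose output must be reproducible by a brute-force
#    re-implementation to float tolerance.

# Frequency response weights on the two-sided FFT grid of length n.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  pmin(f, fs - f)  # fold to [0, fs/2]
}

raised_cosine_mask <- function(f, lo, hi, trans_lo, trans_hi) {
  w <- numeric(length(f))
  pass <- f >= lo & f <= hi
  w[pass] <- 1
  if (trans_lo > 0) {
    ramp <- f >= (lo - trans_lo) & f < lo
    w[ramp] <- 0.5 * (1 + cos(pi * (lo - f[ramp]) / trans_lo))
  }
  if (trans_hi > 0) {
    ramp <- f > hi & f <= (hi + trans_hi)
    w[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - hi) / trans_hi))
  }
  w
}

# Apply a real-valued two-sided frequency mask, zero-phase.
apply_fft_mask <- function(x, mask) {
  n <- length(x)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

# Zero-phase bandpass with raised-cosine transitions plus an optional notch.
fft_filter <- function(x, fs, lo = NULL, hi = NULL, notch = NULL,
                       trans_lo = 0.25, trans_hi = 10, notch_halfwidth = 1,
                       notch_trans = 1) {
  n <- length(x)
  f <- fft_freqs(n, fs)
  mask <- rep(1, n)
  if (!is.null(lo) || !is.null(hi)) {
    lo <- if (is.null(lo)) 0 else lo
    hi <- if (is.null(hi)) fs / 2 else hi
    mask <- raised_cosine_mask(f, lo, hi, trans_lo, trans_hi)
  }
  if (!is.null(notch)) {
    # stop band [notch - hw, notch + hw] with cosine shoulders
    nm <- 1 - raised_cosine_mask(f, notch - notch_halfwidth,
                                 notch + notch_halfwidth,
                                 notch_trans, notch_trans)
    mask <- mask * nm
  }
  apply_fft_mask(x, mask)
}

# Exact rectangular bandpass: keep FFT bins with lo <= |f| <= hi, zero rest.
brick_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- fft_freqs(n, fs)
  mask <- as.numeric(f >= lo & f <= hi)
  apply_fft_mask(x, mask)
}

# Spectrally-shaped 1/f^beta Gaussian noise, scaled to a target RMS.
# beta = 0 degenerates to exactly white Gaussian noise of sd = sigma.
shaped_noise <- function(n, fs, beta, sigma, f_floor = 0.5) {
  if (sigma == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (beta == 0) return(sigma * w)
  f <- fft_freqs(n, fs)
  g <- pmax(f, f_floor)^(-beta / 2)
  g[1] <- 0  # no DC component
  x <- apply_fft_mask(w, g)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * sigma / s
}
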