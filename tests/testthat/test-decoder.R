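# Decoder pipeline: conditioning, Laplacian, least-squares AR fit, band
# amplitude, adaptive normalization, velocity mapping, and the step/rate
# contract.

test_that("conditioning removes 60 Hz and preserves the mu band", {
  fs <- 1000
  tt <- (0:(4 * fs - 1)) / fs
  cfg <- decoder_config()
  mains <- eeg_recording(matrix(sin(2 * pi * 60 * tt), 1), fs, "C3")
  out <- condition(mains, cfg)
  expect_lt(sqrt(mean(out$data^2)) / sqrt(mean(mains$data^2)), 0.05)
  mu <- eeg_recording(matrix(sin(2 * pi * 12 * tt), 1), fs, "C3")
  outmu <- condition(mu, cfg)
  mid <- (fs + 1):(3 * fs)   # avoid window edges
  expect_equal(max(abs(outmu$data[1, mid])), 1, tolerance = 0.02)
  zeros <- eeg_recording(matrix(0, 1, 1000), fs, "C3")
  expect_true(all(condition(zeros, cfg)$data == 0))
  expect_error(condition(eeg_recording(matrix(0, 1, 100), 250, "C3"), cfg),
               class = "mubci_config_error")
})

test_that("small Laplacian rejects common mode and passes the centre", {
  n <- 100
  s <- sin(2 * pi * 12 * (1:n) / 160)
  labs <- c("C3", "FC3", "CP3", "C1", "C5")
  cfg <- quick_decoder()
  same <- eeg_recording(matrix(rep(s, 5), 5, byrow = TRUE), 160, labs)
  expect_equal(small_laplacian(same, "C3", cfg), rep(0, n), tolerance = 1e-12)
  alone <- eeg_recording(rbind(s, matrix(0, 4, n)), 160, labs)
  expect_equal(small_laplacian(alone, "C3", cfg), s)
  expect_error(small_laplacian(alone, "C4", cfg),
               class = "mubci_channel_error")
  bad <- eeg_recording(matrix(0, 2, n), 160, c("C3", "FC3"))
  expect_error(small_laplacian(bad, "C3", cfg),
               class = "mubci_channel_error")
})

test_that("fit_ar recovers known AR coefficients (oracle = truth)", {
  true_sets <- list(c(0.6, -0.3), c(1.3, -0.75), c(0.5, 0.2, -0.3, 0.1))
  for (i in seq_along(true_sets)) {
    coefs <- true_sets[[i]]
    x <- with_seed(50 + i, oracle_ar_series(coefs, 10000))
    m <- fit_ar(x, length(coefs))
    expect_false(m$degenerate)
    expect_lt(max(abs(m$coefficients - coefs)), 0.02)
    expect_equal(m$residual_variance, 1, tolerance = 0.06)
  }
})

test_that("fit_ar handles white noise, sinusoids and degenerate input", {
  x <- with_seed(7, rnorm(4000))
  m <- fit_ar(x, 8)
  expect_true(all(abs(m$coefficients) < 3 / sqrt(length(x))))
  s <- sin(2 * pi * 12 * (0:999) / 160)
  ms <- fit_ar(s, 16)
  expect_lt(ms$residual_variance / var(s), 1e-3)
  md <- fit_ar(rep(2, 100), 4)
  expect_true(md$degenerate)
  expect_equal(md$coefficients, numeric(4))
  expect_error(fit_ar(1:10, 10), class = "mubci_argument_error")
})

test_that("AR band amplitude contrasts in-band against out-of-band", {
  fs <- 160
  x <- with_seed(3, sin(2 * pi * 12 * (0:3999) / fs) + 0.05 * rnorm(4000))
  m <- fit_ar(x[1:64], 16)
  inb <- ar_band_amplitude(m, c(10, 14), fs)
  outb <- ar_band_amplitude(m, c(20, 24), fs)
  expect_gt(inb / outb, 10)
  # white noise: any two equal-width bands roughly equal
  ratios <- vapply(1:50, function(s) {
    w <- with_seed(300 + s, rnorm(400))
    mw <- fit_ar(w, 16)
    ar_band_amplitude(mw, c(10, 14), fs) /
      ar_band_amplitude(mw, c(30, 34), fs)
  }, numeric(1))
  expect_gt(median(ratios), 0.5)
  expect_lt(median(ratios), 2)
  expect_error(ar_band_amplitude(m, c(10, 100), fs),
               class = "mubci_argument_error")
})

test_that("EWMA normalizer is calibrated and tracks steps at its half-life", {
  st <- norm_state(halflife = 2, update_interval = 0.04)
  for (i in 1:10) expect_equal(as.numeric(normalize_feature(st, 5)), 0)
  expect_true(isTRUE(attr(normalize_feature(st, 5), "degenerate")))
  # long-run variance of z on a stationary stream
  st <- norm_state(halflife = 2, update_interval = 0.04)
  x <- with_seed(9, rnorm(50000, mean = 10, sd = 2))
  z <- vapply(x, function(v) as.numeric(normalize_feature(st, v)),
              numeric(1))
  expect_gt(var(z[-(1:2000)]), 0.8)
  expect_lt(var(z[-(1:2000)]), 1.2)
  # step response of the mean tracker: halves in ~halflife seconds
  st <- norm_state(halflife = 2, update_interval = 0.04)
  for (v in with_seed(10, rnorm(5000, 0, 1))) normalize_feature(st, v)
  m0 <- st$m
  target <- (m0 + 5) / 2        # halfway to the new mean of 5
  xs <- with_seed(11, rnorm(5000, 5, 1))
  t_half <- NA
  for (i in seq_along(xs)) {
    normalize_feature(st, xs[i])
    if (st$m >= target) { t_half <- i * 0.04; break }
  }
  expect_equal(t_half, 2, tolerance = 0.2)
})

test_that("control mapping follows the imagery-to-direction convention", {
  cfg <- decoder_config(gain_x = 1, gain_y = 1)
  expect_equal(control_signal(0, 0, cfg), c(vx = 0, vy = 0))
  # right-hand imagery: left-hemisphere ERD (left_z < 0) -> rightward
  expect_equal(control_signal(-1, 0, cfg), c(vx = 1, vy = 0.5))
  # both-hands: bilateral ERD -> upward
  expect_equal(control_signal(-1, -1, cfg), c(vx = 0, vy = 1))
  # relax: bilateral ERS -> downward
  expect_equal(control_signal(1, 1, cfg), c(vx = 0, vy = -1))
  expect_error(control_signal(NA, 0, cfg), class = "mubci_argument_error")
  # monotonicity in the hemispheric difference / sum
  base <- control_signal(-0.2, 0.3, cfg)
  for (dz in c(0.1, 0.5, 1)) {
    up <- control_signal(-0.2 - dz, 0.3, cfg)
    expect_gt(up[["vx"]], base[["vx"]])
    expect_gt(up[["vy"]], base[["vy"]])
  }
})

test_that("decode_recording emits one control state per update interval", {
  p <- quick_params(seed = 14)
  ses <- generate_session(c("REST", "REST"), p)
  cfg <- quick_decoder()
  log <- decode_recording(ses$recording, cfg)
  fs <- 160
  win_n <- round(cfg$window_length * fs)
  step_n <- round(cfg$update_interval * fs)
  expect_equal(nrow(log),
               floor((n_samples(ses$recording) - win_n) / step_n) + 1)
  # one state per update interval, on the sample grid
  expect_equal(diff(log$timestamp), rep(step_n / fs, nrow(log) - 1),
               tolerance = 1e-9)
  expect_true(all(is.finite(log$vx)))
})

test_that("streaming decoder matches warm-up contract and emits per tick", {
  p <- quick_params(seed = 15)
  cfg <- quick_decoder()
  st <- mu_stream(p)
  dec <- decoder_init(cfg, p$sampling_rate)
  tick_n <- round(cfg$update_interval * p$sampling_rate)
  states <- list()
  for (i in 1:30) {
    blk <- stream_imagery(st, "REST", tick_n)
    states <- c(states, decoder_step(dec, blk))
  }
  expect_length(states, 30)
  warm <- vapply(states, `[[`, logical(1), "warmup")
  # warm-up until a full window is buffered, then real output
  win_n <- round(cfg$window_length * p$sampling_rate)
  k <- ceiling(win_n / tick_n)
  expect_true(all(warm[seq_len(k - 1)]))
  expect_false(any(warm[k:30]))
})

test_that("normalizer absorbs the overall mu amplitude scale", {
  fs <- 160
  cfg <- quick_decoder(normalizer_halflife = 5)
  zmeans <- vapply(c(1, 2), function(scale) {
    p <- quick_params(mu_baseline_amp = 20 * scale, seed = 77)
    ses <- generate_session(rep("REST", 6), p)
    log <- decode_recording(ses$recording, cfg)
    mean(log$left_z[-(1:200)])
  }, numeric(1))
  expect_lt(abs(zmeans[1] - zmeans[2]), 0.15)
})
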