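# On-demand synthetic-EEG stream for closed-loop simulation.  The stream
# keeps oscillator phase, frequency-jitter state, background-filter state
# and per-component RNG substreams in an environment, so that two
# consecutive blocks reproduce one block of the combined length (to float
# tolerance; phase is a running sum) and imagery switches ramp the
# hemispheric modulation over `modulation_latency`.
#
# The streamed background is a sum of octave-spaced AR(1) processes driven
# by a shared innovation (a streamable approximation of 1/f^beta noise);
# the offline generator uses exact FFT spectral shaping instead.

#' Initialise a synthetic-EEG stream
#'
#' @param params a [sim_params()] object.
#' @param imagery initial imagery class (default REST).
#' @return a stream-state environment for [stream_imagery()].
#' @export
mu_stream <- function(params, imagery = "REST") {
  st <- new.env(parent = emptyenv())
  st$params <- params
  fs <- params$sampling_rate
  st$fs <- fs
  st$n_total <- 0L
  nch <- length(params$channel_labels)

  # background cascade: octave-spaced AR(1) stages, shared innovation
  fk <- 0.5 * 2^(0:20)
  fk <- fk[fk < fs / 4]
  pk <- exp(-2 * pi * fk / fs)
  ck <- sqrt(1 - pk^2)                       # unit-variance stages
  ak <- fk^((1 - params$background_exponent) / 2)
  # stationary sd of sum(ak * u_k) with shared innovations
  jmax <- min(ceiling(log(1e-8) / log(max(pk))), 2e5)
  gj <- vapply(0:jmax, function(j) sum(ak * ck * pk^j), numeric(1))
  unit <- sqrt(sum(gj^2))
  st$bg_scale <- if (params$background_sigma > 0)
    params$background_sigma / unit else 0
  st$common_scale <- if (params$common_sigma > 0)
    params$common_sigma / unit else 0
  st$bg_p <- pk; st$bg_c <- ck; st$bg_a <- ak
  st$bg_state <- matrix(0, nch, length(pk))
  st$common_state <- numeric(length(pk))

  rho <- exp(-1 / (0.2 * fs))
  st$jit_rho <- rho
  st$jit_sd <- params$freq_jitter_sd * sqrt(1 - rho^2)

  with_seed(params$seed, {
    st$phase_l <- stats::runif(1, 0, 2 * pi)
    st$phase_r <- stats::runif(1, 0, 2 * pi)
    st$line_phase <- stats::runif(nch, 0, 2 * pi)
  })
  # one RNG substream per noise component, so that the per-sample draw
  # order is independent of how the stream is split into blocks
  st$rngs <- lapply(seq_len(3L + nch), function(k)
    with_seed(substream_seed(params$seed, 1000L + k),
              get(".Random.seed", envir = globalenv())))
  st$jit_l <- 0; st$jit_r <- 0

  fac <- class_modulation(imagery, params)
  st$imagery <- imagery
  st$start_l <- fac[["left"]];  st$target_l <- fac[["left"]]
  st$start_r <- fac[["right"]]; st$target_r <- fac[["right"]]
  st$n_switch <- 0L
  st
}

stream_factor_at <- function(start, target, idx, n_switch, ramp_samples) {
  if (ramp_samples <= 0) return(rep(target, length(idx)))
  frac <- pmin(pmax((idx - n_switch) / ramp_samples, 0), 1)
  start + (target - start) * frac
}

#' Pull the next block from a synthetic-EEG stream
#'
#' Switching `imagery` mid-stream ramps the hemispheric modulation factors
#' linearly over `modulation_latency`; oscillators and background are
#' phase/state continuous across blocks.
#'
#' @param state a [mu_stream()] environment (modified in place).
#' @param imagery imagery class for this block.
#' @param block_samples number of samples to generate (> 0).
#' @return an [eeg_recording()] block.
#' @export
stream_imagery <- function(state, imagery, block_samples) {
  if (!is.numeric(block_samples) || block_samples <= 0)
    stop_arg("`block_samples` must be a positive count")
  nb <- as.integer(block_samples)
  p <- state$params
  fs <- state$fs
  ramp <- round(p$modulation_latency * fs)

  imagery <- match.arg(imagery, IMAGERY_CLASSES)
  if (!identical(imagery, state$imagery)) {
    # freeze current factor values, then ramp towards the new targets
    cur_l <- stream_factor_at(state$start_l, state$target_l, state$n_total,
                              state$n_switch, ramp)
    cur_r <- stream_factor_at(state$start_r, state$target_r, state$n_total,
                              state$n_switch, ramp)
    fac <- class_modulation(imagery, p)
    state$start_l <- cur_l; state$target_l <- fac[["left"]]
    state$start_r <- cur_r; state$target_r <- fac[["right"]]
    state$n_switch <- state$n_total
    state$imagery <- imagery
  }

  idx <- state$n_total + seq_len(nb)   # 1-based global sample counter
  env_l <- stream_factor_at(state$start_l, state$target_l, idx,
                            state$n_switch, ramp)
  env_r <- stream_factor_at(state$start_r, state$target_r, idx,
                            state$n_switch, ramp)

  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  draw <- function(k, n) {   # draw from component substream k
    assign(".Random.seed", state$rngs[[k]], envir = globalenv())
    x <- stats::rnorm(n)
    state$rngs[[k]] <- get(".Random.seed", envir = globalenv())
    x
  }

  jl <- as.numeric(stats::filter(draw(1L, nb) * state$jit_sd,
                                 state$jit_rho, method = "recursive",
                                 init = state$jit_l))
  jr <- as.numeric(stats::filter(draw(2L, nb) * state$jit_sd,
                                 state$jit_rho, method = "recursive",
                                 init = state$jit_r))
  state$jit_l <- jl[nb]; state$jit_r <- jr[nb]
  ph_l <- state$phase_l + 2 * pi * cumsum(p$mu_center_freq + jl) / fs
  ph_r <- state$phase_r + 2 * pi * cumsum(p$mu_center_freq + jr) / fs
  state$phase_l <- ph_l[nb] %% (2 * pi)
  state$phase_r <- ph_r[nb] %% (2 * pi)
  mu_l <- p$mu_baseline_amp * env_l * sin(ph_l)
  mu_r <- p$mu_baseline_amp * env_r * sin(ph_r)

  nch <- length(p$channel_labels)
  dat <- matrix(0, nch, nb)
  tt <- idx / fs
  # spatially common background (+ mains), shared by every channel
  wc <- draw(3L + nch, nb)
  common <- numeric(nb)
  for (k in seq_along(state$bg_p)) {
    u <- as.numeric(stats::filter(state$bg_c[k] * wc, state$bg_p[k],
                                  method = "recursive",
                                  init = state$common_state[k]))
    state$common_state[k] <- u[nb]
    common <- common + state$bg_a[k] * u
  }
  common <- state$common_scale * common +
    if (p$line_noise_amp > 0)
      p$line_noise_amp * sin(2 * pi * 60 * tt + state$line_phase[1]) else 0
  for (i in seq_len(nch)) {
    w <- draw(2L + i, nb)
    acc <- numeric(nb)
    for (k in seq_along(state$bg_p)) {
      u <- as.numeric(stats::filter(state$bg_c[k] * w, state$bg_p[k],
                                    method = "recursive",
                                    init = state$bg_state[i, k]))
      state$bg_state[i, k] <- u[nb]
      acc <- acc + state$bg_a[k] * u
    }
    dat[i, ] <- common + state$bg_scale * acc
  }
  if (had) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())

  dat <- add_sources(dat, p$channel_labels, mu_l, mu_r, p$leakage)
  state$n_total <- state$n_total + nb
  eeg_recording(dat, fs, p$channel_labels,
                start_time = (idx[1] - 1) / fs)
}
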