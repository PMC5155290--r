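---
title: "mubci: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mubci: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package simulates

`mubci` is a desk-testable re-creation of a sensorimotor-rhythm
brain-computer interface (BCI) for sequential reach-and-grasp control.
A trained user modulates the amplitude of the mu rhythm (here the upper mu
band, 10-14 Hz) over the left and right motor cortices by kinesthetic
motor imagery: imagining right-hand movement desynchronizes the
contralateral (left, electrode C3) mu rhythm, left-hand imagery the right
hemisphere (C4), both hands both hemispheres, and deliberate relaxation
produces a bilateral power *increase* (event-related synchronization,
ERS). An online decoder turns the two hemispheric band amplitudes into a
two-axis velocity command; a task engine implements target selection by
*hover dwell* (stay within a 3 cm disc for 2 s) and chains low-dimensional
steps into reach-and-grasp and reach-and-release sequences.

Because no human is in the loop, the package ships a *simulated subject*:
a seeded synthetic-EEG generator whose statistics embody exactly the
modulation structure above. Everything downstream — the decoder, the task
engine, the ERD/ERS maps, the chance-level machinery — operates on that
synthetic signal exactly as it would on recorded data.

# The synthetic-EEG model

Each hemisphere carries one mu source,

$$ s_h(t) = A\,m_h(t)\,\sin\!\Big(\varphi_0 + 2\pi\!\int_0^t (f_0 + j(\tau))\,d\tau\Big), $$

an amplitude-modulated narrowband oscillator rather than filtered noise:
this is the simplest model whose band power is exactly controllable, which
the calibration tests rely on. Its parameters (all in `sim_params()`):

* `mu_center_freq` ($f_0$, default 12 Hz) with a slow AR(1) frequency
  jitter $j(t)$ (`freq_jitter_sd`, default 0.3 Hz, ~200 ms correlation
  time) so the rhythm has a realistic finite bandwidth;
* `mu_baseline_amp` ($A$, default 20 uV peak at the source);
* the class-dependent modulation factor $m_h(t)$: 1 at rest,
  $1-\texttt{erd\_depth}$ during ERD (default depth 0.5), $1+\texttt{ers\_gain}$
  during ERS (default 0.2). Band *power* therefore scales by
  $(1-d)^2$ and $(1+g)^2$ — the closed forms (-75 % and +44 % at the
  defaults) that the acceptance tests assert;
* `modulation_latency` (default 0.5 s): the factor ramps linearly from cue
  onset, because empirical ERD builds up over a few hundred milliseconds
  after the target appears; the exact latency is not published, so it is a
  parameter.

The background has three components per channel: spatially *common*
1/f-shaped Gaussian noise (`common_sigma`, default 15 uV RMS), independent
1/f noise (`background_sigma`, default 5 uV RMS), and a common 60 Hz mains
sinusoid (`line_noise_amp`, default 1 uV). The split into common and
independent parts matters: the small Laplacian subtracts the mean of four
neighbours and therefore cancels the common component while attenuating
the source only by the leakage factor. Without a common component a
Laplacian derivation could never improve mu SNR over the raw channel —
real EEG background is dominated by shared (reference and
volume-conducted) activity, and the generator must reproduce that one
property for the spatial filter to be testable. Neighbour channels carry
`leakage` (default 0.5) times the nearest source plus their own noise; no
head model is claimed.

Defaults were chosen once, as a well-expressed post-training mu rhythm:
a 20 uV source against 5 uV independent noise leaves the 10-14 Hz band
power dominated by the rhythm, so the measured ERD percentage tracks the
$(1-d)^2$ closed form to within a few points. The residual in-band noise
still biases ratios slightly toward baseline; the test suite asserts both
the idealized limit (at low background) and the analytic noisy-case
prediction, so a green test documents precisely what it establishes.

**RNG discipline.** One root seed; each trial draws from a substream
derived by a counter, so trials are reproducible regardless of order. The
streaming generator keeps per-component RNG substreams so that the
generated signal is independent of how it is sliced into blocks; block
concatenation is reproducible to float tolerance (the phase accumulator is
a running sum, so exact bitwise equality across different block splits is
not guaranteed — same-call determinism is bitwise).

**What the generator does not emulate:** ocular/muscle artifacts,
electrode drift or popping, beta/gamma activity, inter-subject
variability, non-stationary fatigue effects, or any volume-conduction
geometry beyond the single leakage coefficient. Green closed-loop tests
therefore establish internal consistency of decoder + engine, not
human-level performance claims.

# The online decoder

Per 40 ms update (the default `update_interval`; the real system's update
rate is unpublished), on the latest 400 ms window of each Laplacian
channel:

1. zero-phase conditioning, 0.5-200 Hz bandpass plus 60 Hz notch. With no
   filter-design package in the dependency stack, filtering is FFT-based
   with raised-cosine transition bands — zero-phase by construction, mu
   passband flat to < 2 %, 60 Hz residual < 5 %;
2. small Laplacian at C3 and C4 (centre minus the mean of FC3/CP3/C1/C5
   and FC4/CP4/C2/C6; the neighbour set is configurable because none is
   published);
3. an order-16 autoregressive model fitted by least squares (covariance
   method: the design matrix of lagged samples is solved via normal
   equations with a relative ridge of 1e-8; Yule-Walker is *not* used
   because it does not minimize the squared prediction error on the
   window);
4. the AR amplitude spectrum
   $\sqrt{\sigma_e^2}/\lvert 1-\sum_k w_k e^{-i2\pi f k/f_s}\rvert$
   averaged over a 1 Hz grid spanning 10-14 Hz;
5. adaptive normalization: exponentially weighted mean and variance with
   half-life `normalizer_halflife` (default 20 s), updated during feedback
   periods, giving a z-score per hemisphere. The mapping needs a zero-mean
   signal and the source system's normalizer is unspecified; an EWMA
   z-score is the simplest adaptive choice and its calibration (long-run
   z variance near 1, step response with the configured half-life) is
   tested;
6. the linear velocity map
   $v_x = g_x(z_R - z_L)$, $v_y = -g_y(z_L + z_R)/2$: right-hand imagery
   (ERD at C3, $z_L<0$) moves right, both-hands imagery up, relaxation
   down. The vertical formula is this package's design — the source
   describes the direction semantics but never writes the equation. Gains
   default to 5 cm/s per z-unit so a well-modulated subject (|z| around
   1.5) moves near the robot's nominal 8 cm/s.

# Task engine

Discrete time, `tick` = decoder update interval. The cursor integrates
the commanded velocity, clipped to the 32 cm square workspace. Selection
requires *continuous* presence within `hover_radius` (3 cm) of a target
centre for `hover_duration` (2 s; 1 s in the fast shelf variant): the
dwell clock counts whole tick intervals from the entry sample and resets
whenever the disc is exited, so a selection can never take less than the
dwell time. Trials end HIT (cued target selected), MISS (another target)
or ABORT at the 12 s feedback timeout.

Two boundary conventions were genuinely open:

* *Start-inside discs.* In no-hover chance variants ("selection on first
  disc entry") a cursor starting on the centre target would self-select at
  t = 0; selection is therefore entry-based — the disc must be entered
  from outside. With a dwell requirement the opposite convention is used:
  holding still inside the disc for the dwell time *is* the selection
  gesture (this also matches the five-target paradigm, where the centre
  target would otherwise be unselectable without an excursion).
* *Ideal completion time.* The dwell clock starts at the disc boundary,
  so the ideal-policy time to hit is
  $(d - r)/v + \text{hover}$ (tick-quantized) for distance $d$, radius $r$,
  speed $v$ — not $d/v + \text{hover}$; the engine's dwell contract wins
  over the simpler closed form.

Sequences: reach-and-grasp is a 2-D reach followed by a 1-D vertical
descent from 17 cm that must settle within `grasp_tolerance` (2 cm) for
the dwell time; reach-and-release chains four steps (table reach, grasp,
shelf reach, release), restarting from scratch on any failure. Run caps
follow the paradigms: 13 grasped blocks for fixed-target runs, 10 for
random targets, 6 moves for shelf runs. The fast variant scales all phase
durations by 2/3 and raises the robot speed limit from 8 to 20 cm/s; the
robot tracker chases the commanded position at the limit and logs its lag.
Random targets cycle the four quadrants in shuffled blocks of four,
uniformly within the quadrant outside two corner exclusion triangles
(10 % of the workspace each — the inaccessible regions are not
dimensioned in the source, so their shape is configuration).

# ERD/ERS maps

For each 3 Hz-wide bin (1 Hz steps across 8-26 Hz) and channel: zero-phase
rectangular-mask bandpass, segmentation around feedback onset (cue at
-3 s, baseline -4.5..-3 s for the cursor paradigm; cue at -2.5 s,
baseline -4..-2.5 s for the robot paradigm), per-trial linear detrend
(method flag: none/constant/linear), squaring, a 100 ms moving average,
decimation to a 50 ms grid, and averaging over trials. Percent change is
$100\,(A_j - R)/R$ against the baseline mean $R$; values are bounded below
by -100 % and unbounded above. Maps default to the small-Laplacian
derivation of C3/C4 (like the online feature), which keeps the in-band
background contribution small relative to the rhythm.

Significance masking bootstraps trials (seeded, weight-matrix
implementation). The interval variant was left open by the source and is
a parameter: the default is the studentized bootstrap-SE t-interval
(`ci_type = "tboot"`), because in a 20-seed null calibration experiment
(pure-noise trials, 100 per seed, 4200 cells) it was the only standard
variant whose false-positive cell rate (5.6 %) stayed within twice the
binomial standard error of the nominal 5 %; the percentile (5.8 %), basic
(6.3 %) and normal (6.0 %) intervals all run anti-conservative for this
ratio statistic at realistic trial counts. Percentile/basic/normal remain
selectable.

The generated `erd_depth` can be recovered from a map as
$\hat d = 1 - \sqrt{1 + \text{ERD}/100}$ over feedback-period mu cells;
the acceptance suite requires $|\hat d - d| < 0.05$ at 100 trials for
$d \in \{0.2, 0.4, 0.6\}$.

# Chance levels and metrics

Percent valid correct (PVC) is hits over hits-plus-misses; aborts are
excluded. Chance levels are estimated by Monte-Carlo: the paradigm runs
under an intent-free policy — an i.i.d. zero-mean Gaussian velocity per
tick (default), or the full decoder fed a resting-state synthetic stream
(faithful to the resting-subject protocol, slower) — with hover disabled
("paradigms without hovering time": selection on first entry) and a
uniformly random cue each trial. Because the cue is independent of the
policy, the expected PVC is exactly 1/(number of targets) regardless of
layout asymmetries or the policy's velocity scale; the scale (default
20 cm/s per axis) only sets the fraction of trials that end in a valid
selection before the timeout, i.e. the Monte-Carlo efficiency. The
empirical values reported for resting humans (25.3 % and 22.5 % for the
four- and five-target paradigms) came from real resting EEG; the
simulation approaches the theoretical 25 % / 20 %, and no test asserts the
human empirical numbers.

# Numerical and validation notes

* Seeds below 2^31; every user-facing stochastic operation takes an
  explicit seed or uses `with_seed()`.
* `fit_ar` flags constant (rank-deficient) windows degenerate and returns
  zero coefficients; the normalizer returns z = 0 and a degenerate flag
  while its variance is zero; warm-up decoder updates repeat the previous
  control state with `warmup = TRUE`.
* Event timestamps always land on the sample grid; event tables are
  validated for phase ordering and trial overlap on read.
* EDF I/O is a minimal in-package 16-bit implementation (no EDF package
  exists in the dependency stack); round-trip error is bounded by one
  digital step per channel. Delimited text round-trips exactly.
* Test suites run at 160-250 Hz sampling instead of the nominal 1 kHz to
  stay within CI budgets; all asserted quantities are rate-independent
  (band-power ratios, percentages, closed-form times).

# Known limitations

Single-subject statistics only (no group-level tests on human data); no
3-D continuous control; no artifact model, so artifact-rejection behaviour
is untested; the closed-loop "subject" switches imagery instantaneously
with a fixed strategy (idle inside the hover disc, dominant-axis imagery
outside), which is a crude model of human target-approach behaviour; and
chance-level simulations reproduce the theoretical, not the
human-empirical, values.
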