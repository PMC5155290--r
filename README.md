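# mubci

Simulation and decoding of a mu-rhythm motor-imagery brain-computer
interface (BCI) for sequential reach-and-grasp control — as a fully
desk-testable closed loop, with no hardware and no human in the loop.

## Who this is for

Researchers and engineers who want to prototype, test or teach
sensorimotor-rhythm BCI pipelines: the package provides a seeded
"simulated subject" (synthetic multichannel EEG whose mu rhythm shows the
canonical task-locked modulation), the complete online decoding chain, a
discrete-time task engine for hover-dwell target selection and sequential
reach-and-grasp / reach-and-release paradigms, offline ERD/ERS
time-frequency analysis with bootstrap significance masking, and
performance metrics including Monte-Carlo chance-level estimation.

## The model in brief

Imagery of the left hand, right hand, both hands, or relaxation modulates
the upper-mu (10–14 Hz) rhythm over motor cortex: unilateral imagery
produces contralateral event-related desynchronization (ERD, a power
*decrease*), both-hands imagery bilateral ERD, relaxation bilateral
synchronization (ERS, a power *increase*). The decoder estimates each
hemisphere's band amplitude from small-Laplacian-filtered C3/C4 with a
sliding-window order-16 least-squares autoregressive (AR) spectrum
(400 ms window), normalizes it to a z-score with an exponentially
weighted tracker, and maps the pair linearly to velocity:

    vx = gain_x * (z_C4 - z_C3)        # right-hand imagery -> rightward
    vy = -gain_y * (z_C3 + z_C4) / 2   # bilateral ERD -> up, ERS -> down

Targets are selected by hovering within a 3 cm disc for 2 s; reach-and-
grasp chains a 2-D reach with a 1-D descent. ERD/ERS maps express band
power as percent change against a pre-cue baseline,
`100 * (A - R) / R`, so an amplitude attenuation of `1 - d` appears as
`100 * ((1-d)^2 - 1)` percent (−75 % at `d = 0.5`). Percent valid correct
(PVC) is hits over hits-plus-misses, aborts excluded.

## Worked example

```r
library(mubci)

# a 100-trial session from the simulated subject (ERD depth 0.5, ERS gain 0.2)
p <- sim_params(sampling_rate = 250, line_noise_amp = 0,
                erd_depth = 0.5, ers_gain = 0.2, seed = 42)
plan <- with_seed(42, sample(rep(c("LEFT_HAND", "RIGHT_HAND",
                                   "BOTH_HANDS", "RELAX"), each = 25)))
ses <- generate_session(plan, p)
ses$recording
#> <eeg_recording> 10 channels x 250000 samples @ 250 Hz (1000.00 s)
#>   channels: C3, FC3, CP3, C1, C5, C4, FC4, CP4, C2, C6

# ERD/ERS maps, mean percent change in feedback-period mu cells
maps <- condition_maps(ses$recording, ses$events,
                       erd_params(n_boot = 500), seed = 1)
fb <- c(0.5, 3.5)
for (cond in c("LEFT_HAND", "RIGHT_HAND", "BOTH_HANDS", "RELAX"))
  cat(sprintf("%-10s  C3 %6.1f %%   C4 %6.1f %%\n", cond,
              map_band_mean(maps[[cond]]$C3, fb),
              map_band_mean(maps[[cond]]$C4, fb)))
#> LEFT_HAND   C3   -3.0 %   C4  -74.1 %
#> RIGHT_HAND  C3  -75.2 %   C4    0.6 %
#> BOTH_HANDS  C3  -71.2 %   C4  -72.5 %
#> RELAX       C3   45.4 %   C4   47.5 %
```

Unilateral imagery shows clean contralateral ERD near the −75 % closed
form for depth 0.5, both-hands imagery bilateral ERD, relaxation
bilateral ERS near the +44 % closed form for gain 0.2. The generator's
depth is recoverable from the map:

```r
recover_erd_depth(maps$BOTH_HANDS$C3)
#> [1] 0.463
```

Chance level of the four-target cursor paradigm under an unbiased
random-walk policy (no hover, 2000 trials):

```r
r <- chance_level("cursor2d", n_trials = 2000, seed = 7)
cat(sprintf("PVC %.1f %% (95%% CI %.1f-%.1f, %d valid trials)\n",
            r$pvc, r$ci[1], r$ci[2], r$n_valid))
#> PVC 25.8 % (95% CI 23.7-27.8, 1790 valid trials)
```

close to the theoretical 25 % for four targets.

## Command line

```sh
Rscript -e 'q(status = mubci::bci_main())' simulate --seed 7 --out demo
Rscript -e 'q(status = mubci::bci_main())' run-loop --stage grasp4 --policy ideal --seed 3 --out demo
Rscript -e 'q(status = mubci::bci_main())' chance --stage cursor2d --no-hover --n 2000 --seed 1
```

(or via the launcher `inst/cli/mubci`). Exit codes: 0 ok, 2 bad
arguments, 3 validation failure, 4 I/O failure.

## Package layout

- `R/synthetic-eeg.R`, `R/stream.R` — offline and streaming signal
  generator
- `R/decoder.R` — conditioning, Laplacian, AR spectrum, normalizer,
  velocity map
- `R/task-engine.R`, `R/closed-loop.R` — trials, sequences, placement,
  robot tracking, simulated subject
- `R/erd.R` — ERD/ERS maps with bootstrap masks
- `R/metrics.R` — PVC, chance levels, run summaries
- `R/io.R`, `R/cli.R` — EDF/TSV/JSON I/O and the CLI
- `vignettes/mubci-methods.Rmd` — models, parameter choices, numerical
  decisions, limitations
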