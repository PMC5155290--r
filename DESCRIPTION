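Package: mubci
Title: Simulation and Decoding of Mu-Rhythm Motor-Imagery Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("BCI", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-testable closed-loop sensorimotor-rhythm brain-computer
    interface (BCI) stack. Provides a seeded synthetic-EEG generator whose
    mu rhythm (10-14 Hz) over C3/C4 shows contralateral event-related
    desynchronization (ERD) for unilateral hand imagery, bilateral ERD for
    both-hands imagery and bilateral event-related synchronization (ERS)
    for relaxation; an online decoder (notch/bandpass conditioning, small
    Laplacian, sliding-window least-squares autoregressive spectral
    estimation, adaptive normalization, linear power-to-velocity mapping);
    a discrete-time task engine for hover-dwell target selection and
    sequential reach-and-grasp / reach-and-release paradigms; offline
    ERD/ERS time-frequency maps with bootstrap significance masking; and
    performance metrics including percent valid correct (PVC) and
    Monte-Carlo chance-level estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
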