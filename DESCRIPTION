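Package: abcpe
Title: Amplitude-Based Characteristic Parameter Extraction for
    Electromagnetic-Induction Cerebral Edema Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal analysis of two-port transmission
    (S21) amplitude-frequency sweeps acquired by electromagnetic-induction
    sensors for cerebral edema monitoring. Implements amplitude-based
    characteristic parameter extraction: resonance peak tracking, 3 dB
    (half-power) bandwidth location by linear interpolation, band mean
    amplitudes, and five dimensionless characteristic parameters (alpha,
    beta, gamma, delta, rho) measured relative to each subject's baseline
    sweep. Provides Euclidean combination scoring of parameter subsets
    after mapping to [-1, 1], ROC/AUC evaluation with Youden operating
    points, exhaustive evaluation of all 31 parameter combinations for
    three study comparisons, Touchstone (.s2p) and long-format CSV I/O,
    and a synthetic cohort simulator with Lorentzian resonance curves and
    two-phase (acute/chronic) drift trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
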