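---
title: "Characteristic parameter extraction and combination scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characteristic parameter extraction and combination scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the model behind the package, the numerical
decisions that were genuinely open, and what the simulator does and does
not emulate. It states no result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

An electromagnetic-induction sensor pair and the head form a two-port
network; a vector network analyzer sweeps the excitation frequency
(1–100 MHz, 1060 points in the default design) and records the forward
transmission amplitude |S21| in dB. Near the coupling resonance the
amplitude-frequency curve is a single peak; intracranial change
perturbs the equivalent load impedance and therefore the peak's height,
position and width together. Rather than modeling that impedance, the
package works entirely at curve level: each sweep is reduced to the
resonance peak A(f), its 3 dB (half-power) band [f', f''] with width
F = f'' − f' and grid-point count N, and band-mean amplitudes; the five
characteristic parameters α, β, γ, δ, ρ are the fractional changes of
A, f, F, and the two band means relative to the subject's own baseline
sweep at t0. Self-referencing removes static inter-subject differences
(coil placement, anatomy) and makes all five parameters exactly zero at
baseline — which is also why baseline records are excluded from every
analysis window: they would inject identical degenerate zeros into both
classes.

Two of the parameters deserve comment. δ averages the current sweep
over the *baseline* band F0, so it sees amplitude change at fixed
frequencies; ρ averages over the *current* band F_i, so it follows the
peak. Whenever the band does not move the two coincide (a tested
invariant). All ratios are applied literally to dB amplitudes, which are
typically negative: a +1 dB rise at A0 = −20 dB gives α = −0.05. The
sign flip is deliberate — the downstream classifier is sign-agnostic
(scores are magnitudes after mapping, and ROC orientation is chosen
empirically), so consistency matters more than sign aesthetics.

## Numerical decisions

**Half-power crossings are interpolated.** On a discrete grid no sample
satisfies the defining equality |S21|(f') = A − 3 exactly. The package
walks outward from the peak to the first sample below the level and
places the crossing by linear interpolation between the bracketing
samples. This stabilizes F against grid quantization; N, by contrast,
counts raw grid points inside [f', f''], staying faithful to the
"number of frequency points contained" definition. A small relative
tolerance (1e-9) keeps a crossing that lands numerically on a grid
point from dropping that point.

**Innermost crossings.** If noise or side lobes make the curve re-cross
the −3 dB level, the crossings nearest the peak are used, keeping the
band contiguous around the characteristic frequency.

**Ties and degeneracies.** A tied maximum resolves to the lowest
frequency (determinism); an all-flat curve is rejected; a peak at the
sweep edge is flagged and necessarily fails band extraction on that
side with an error naming the side. Within a cohort such per-record
failures are collected into an error report rather than aborting the
run, since a 24 h series with one unusable sweep is still a usable
series. How to treat sweeps whose −3 dB level is never reached inside
the sweep range is this package's own choice; an alternative would be
to clamp the band at the sweep edge, which would silently bias γ
downward.

**Baseline band means.** Both ā0 and ā_i are means over the N0 grid
points inside F0, so δ compares like with like; ā_i' uses the N_i
points inside F_i.

## Combination scoring and ROC

For a parameter subset of size ≥ 2, each member is divided by the
pooled maximum absolute value over **all** observations of the
comparison — both classes together — and the score is the Euclidean
norm of the mapped vector, which therefore lies in [0, sqrt(k)]. The
pooled (rather than per-class) normalization is a deliberate choice:
normalizing each class by its own maximum would put the two classes on
different scales, and no single threshold could act on both. A
single-parameter subset is scored on the raw value, preserving its
native threshold semantics. A parameter that is identically zero across
observations contributes zero with a warning rather than 0/0.

The ROC is built by an explicit threshold sweep over midpoints between
consecutive distinct scores plus ±Inf sentinels; the AUC is the
trapezoidal area, which equals the tie-aware Mann–Whitney pair
statistic (a tested equivalence, and cross-checked against pROC).
Orientation is chosen so the reported AUC is ≥ 0.5, with the direction
recorded; the orientation-free area `auc_raw` is also reported, because
a max-oriented AUC is biased above 0.5 under the null and cannot be
used to check chance-level calibration. The operating point is the
Youden maximizer (J = sensitivity + specificity − 1), ties broken
toward higher sensitivity; Youden is a documented choice, not the only
defensible one. The observation unit is one (subject, time point)
measurement — the early-detection analysis with 30-min sampling has
exactly two rounds of data per subject within the first hour, which
only makes sense per-measurement.

Time windows are half-open on the left: full (0, 24], early (0, 1],
acute (0, 6], chronic (6, 24], so a record at exactly 6 h is acute.
The boundary assignment is a convention fixed here and tested; nothing
downstream is sensitive to it beyond single records.

## What the simulator emulates

Each subject's baseline curve is a Lorentzian in linear power with
closed-form half-power points. With the floor far below the peak, the
−3 dB width is narrower than the half-power width by the constant
factor sqrt(10^0.3 − 1) ≈ 0.9976 at every time point, so fractional
bandwidth changes (γ) are unaffected by the 3 vs 3.0103 dB convention;
extraction uses the literal −3 dB level and tests carry the residual in
their tolerances.

Defaults mirror the target measurement protocol: 10 experimental + 4
control subjects, one sweep per 30 min for 24 h (49 time points), 1060
frequency points over 1–100 MHz. Edema subjects drift along a
two-segment piecewise-linear trajectory — 70% of each endpoint change
realized by 6 h, the remainder by 24 h — encoding acute-phase dynamics
strictly faster than chronic-phase dynamics; controls are stationary up
to noise. Endpoint effects (peak +8% of |A0| in dB, center frequency
+1.5%, bandwidth +25%) and the noise model (0.05 dB i.i.d. per point,
plus small per-record jitter of the true peak, center and width) are
package defaults chosen to be physically plausible for a resonant coil
sensor at these frequencies; they are not measured values, and the
per-record ground truth is attached to every simulated cohort so the
defaults remain auditable. Baseline priors (A0 ~ N(−20, 1) dB,
f0 ~ N(55, 3) MHz, FWHM ~ N(8, 1) MHz, floor −55 dB) keep the 3 dB band
fully resolved inside the sweep. Per-subject RNG streams are derived
from the master seed as (seed + 7919·index) mod 2^31−1, so a subject's
draws are independent of cohort size.

What the simulator does **not** emulate: real rabbit data show a
secondary acceleration around 15–18 h that has no published mechanism
or magnitude and is not modeled by default; physiological compensation,
drift in sensor placement, temperature effects, and non-Lorentzian line
shapes are likewise absent. Passing tests therefore demonstrate that
the pipeline recovers known structure from data shaped like the
protocol — not that real cerebral edema is detectable at any particular
accuracy. Measured-cohort AUCs cannot be reproduced here because the
underlying animal data are not deposited.

## Problem sizes used in tests

Unit tests run on reduced designs (hundreds of grid points, a handful
of subjects and time points) that exercise every code path; full-design
cohorts (14 subjects × 49 × 1060) are used where the property under
test concerns the study design itself: chance-level calibration of a
zero-effect cohort (averaged over 10 seeds, on the orientation-free
AUC) and detectability/phase separation of the default edema cohort.
The oracle-equivalence tests compare extraction against an
independent loop-based reimplementation on 100 random noisy sweeps at
1e-9 relative tolerance; ROC equivalence against hand-counted
Mann–Whitney statistics runs on 50 random tied score sets at 1e-12.

## Known limitations

- Touchstone support is v1 `.s2p` only (the VNA export format of the
  instruments in question); v2 `.ts` files are out of scope.
- Phase data are discarded on read; the analysis is amplitude-only by
  design.
- Only the global maximum is tracked; multi-peak curves are reduced to
  their dominant resonance.
- No smoothing is applied before extraction, matching the analysis the
  package implements; heavily noisy sweeps widen γ's variance
  accordingly.
- AUCs are point estimates; no confidence intervals or cross-validation
  are provided.
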