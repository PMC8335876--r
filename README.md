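# abcpe

Amplitude-based characteristic parameter extraction for
electromagnetic-induction cerebral edema monitoring.

## The problem

Cerebral edema — pathological accumulation of intracranial fluid after
neurological injury — changes the bulk dielectric properties of the head.
A non-contact electromagnetic-induction sensor (an excitation/receiving
coil pair driven by a vector network analyzer) sees this as a change in
the forward transmission coefficient S21 of the two-port network formed
by the coils and the head. Tracking a single frequency or the resonance
shift alone is unreliable, because intracranial pathology perturbs the
equivalent load impedance in several coupled ways at once. This package
implements a multi-frequency alternative: it reduces each amplitude
sweep |S21|(f) (dB, typically 1–100 MHz) to five dimensionless
characteristic parameters measured against the subject's own first
(baseline, t0) sweep, and classifies measurements by combining these
parameters.

For a sweep at time t_i, with peak amplitude A_i at characteristic
frequency f_i, 3 dB (half-power) band [f_i', f_i''] of width
F_i = f_i'' − f_i', mean amplitude ā_i over the **baseline** band F_0 and
mean amplitude ā_i' over the **current** band F_i:

- α = (A_i − A_0) / A_0 — peak amplitude change
- β = (f_i − f_0) / f_0 — characteristic frequency shift
- γ = (F_i − F_0) / F_0 — half-power bandwidth change
- δ = (ā_i − ā_0) / ā_0 — mean amplitude change over the baseline band
- ρ = (ā_i' − ā_0) / ā_0 — mean amplitude change over the current band

The ratios act literally on dB values, which are usually negative, so a
rising peak gives a negative α; classification is sign-agnostic. For a
subset of parameters, each is mapped to [−1, 1] by its pooled maximum
absolute value and observations are scored by the Euclidean norm of the
mapped vector; a threshold sweep then yields the ROC curve, its AUC, and
the Youden operating point. All 31 non-empty subsets of {α, β, γ, δ, ρ}
are evaluated for three study questions: edema vs control over 24 h,
edema vs control within the first hour, and acute (0–6 h] vs chronic
(6–24 h] phase within the edema group.

Because no raw cohort of this kind is publicly deposited, the package
ships a simulator that generates longitudinal cohorts with the matching
physical structure — Lorentzian-in-power resonance curves whose peak,
center frequency and bandwidth drift fast in the acute phase and slowly
in the chronic phase — so the full pipeline is testable end to end, with
ground truth attached.

## Worked example

```r
library(abcpe)

cohort <- simulate_cohort(seed = 1)   # 10 Exp + 4 Con, 49 sweeps x 1060 points
params <- extract_series(cohort)
params
#> # A tibble: 672 × 8
#>    subject group time_h     alpha     beta     gamma      delta        rho
#>    <chr>   <chr>  <dbl>     <dbl>    <dbl>     <dbl>      <dbl>      <dbl>
#>  1 Con01   Con      0.5 -0.000239  0.00835  0.000263 -0.000319  -0.000319
#>  2 Con01   Con      1    0.00151  -0.00334  0.0160   -0.000965   0.00145
#>  3 Con01   Con      1.5  0.000425  0        0.0346   -0.00205    0.00143
#> # i 669 more rows
```

One row per non-baseline measurement: a control subject's parameters
hover near 0 (only sensor noise), while experimental subjects drift away
from 0 as edema develops. Evaluating every parameter combination for
24 h detection:

```r
tbl <- evaluate_all_combinations(params, "detect_24h")
tbl[tbl$combination == "gamma+delta+rho", c("combination", "auc", "sensitivity", "specificity")]
#>   combination      auc sensitivity specificity
#> 1 gamma+delta+rho 0.998       0.977           1
```

The bandwidth/mean-amplitude combination {γ, δ, ρ} separates the
simulated edema group from controls almost perfectly: AUC 0.998, with
97.7% sensitivity and 100% specificity at the Youden threshold. The same
scores explicitly:

```r
obs <- build_observations(params, "detect_24h")
roc <- roc_analysis(map_and_score(obs, c("gamma", "delta", "rho")))
roc
#> ROC analysis (480 positive / 192 negative observations)
#>   AUC: 0.9983 (orientation: increasing)
#>   Youden point: threshold 0.1635, sensitivity 0.977, specificity 1.000

glance(roc)    # one-row tibble; tidy(roc) gives the full threshold sweep
autoplot(roc)  # ROC curve with the Youden point marked
```

I/O helpers read and write Touchstone v1 `.s2p` files
(`read_touchstone()`, `write_touchstone()`, formats RI/MA/DB), long
cohort CSVs (`read_cohort_csv()`) and per-subject `.s2p` directory trees
(`read_cohort_touchstone()`). `run_pipeline(outdir, seed)` executes
simulate → extract → evaluate in one call and writes every artifact
(cohort, ground truth, parameters, 31-row combination tables, text
report, config snapshot) to disk; `inst/cli/abcpe.R` exposes the same
steps as a shell command.

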