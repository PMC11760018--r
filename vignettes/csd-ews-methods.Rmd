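---
title: "Detecting critical slowing down in post-extubation vital signs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting critical slowing down in post-extubation vital signs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdews)
```

## The scientific question

When mechanical ventilation is withdrawn in a paediatric intensive care
unit, a fraction of children fail the extubation and need re-intubation
within 48 hours. If that failure is a *critical transition* — a bifurcation
in the physiological dynamics — then dynamical-systems theory predicts a
measurable precursor: **critical slowing down (CSD)**. As the dominant
eigenvalue of the linearized dynamics approaches zero, perturbations decay
ever more slowly, so the *variance* and the *lag-1 autocorrelation* of
fluctuations around the physiological baseline should rise ahead of the
transition. `csdews` implements the complete analysis that tests this
prediction on high-frequency (5-second) heart-rate, respiratory-rate and
mean-blood-pressure monitor data, together with a synthetic cohort
generator that realizes the hypothesized dynamics so every stage can be
validated end to end.

## The linearized model

Fluctuations `x` around equilibrium are modelled as an Ornstein–Uhlenbeck
(OU) process

$$\frac{dx}{dt} = -\lambda x + \sigma \epsilon,$$

with decay rate $\lambda > 0$ (the magnitude of the dominant eigenvalue),
noise amplitude $\sigma$, and white noise $\epsilon$. Its stationary
moments are

$$\mathrm{Var}(x) = \frac{\sigma^2}{2\lambda}, \qquad
  \mathrm{ACF}(\tau) = e^{-\lambda\tau},$$

so as $\lambda \to 0$ (the approach to a fold bifurcation) the variance
diverges and the autocorrelation tends to 1. These closed forms
(`ou_moments()`) are the package's ground truth: simulations
(`simulate_ou()`) use the *exact* OU discretization
$x_{k+1} = e^{-\lambda\Delta t}x_k + e_k$,
$e_k \sim N\!\big(0, \tfrac{\sigma^2}{2\lambda}(1 - e^{-2\lambda\Delta t})\big)$,
which has no step-size bias even on the coarse 5-s grid. A note on sign
conventions: the decay form above is the only reading under which the
stationary moments exist, so "$\lambda \to 0$" is always interpreted as the
decay rate approaching zero.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces labelled records in four clinical cohorts
(1: failed extubation, re-intubated, survived; 2: successful controls,
assigned pseudo-re-intubation times by resampling the failure duration
distribution so interval lengths match; 3: died without re-intubation; 4:
re-intubated and died). Per record and variable it simulates baseline +
slow sinusoidal drift + OU residual, then injects missing-data runs
(geometric lengths, a mix of short and long gaps so both preprocessing
branches are exercised). Failure records carry a decay-rate ramp, linear in
time from `lam_start` to `lam_end`, reaching its minimum exactly at the
endpoint.

Defaults, chosen once as plausible paediatric settings (they are
configuration values, not estimates): baselines HR 120 BPM, RR 30 BrPM,
ABP 60 mmHg; drift amplitudes 5/2/3 with a 2-h period; noise amplitudes
$\sigma$ = 3/1.5/2 signal-units·s^-1/2^; $\lambda$ from 0.5 /s down to
0.005 /s for failures; record durations lognormal with median 4 h,
truncated to 2–24 h (so every default record passes the 120-min
eligibility rule); default cohort sizes 101 failures vs 1475 controls,
mirroring the evaluable heart-rate cohorts of the motivating study.

The generator reproduces the *statistical* structure the analysis assumes —
it is not a mechanistic cardio-respiratory model. Real monitor data differ
in ways the synthetic cohort deliberately omits: non-sinusoidal and
non-stationary baselines (sleep/wake, interventions, medication), artefacts
that are not i.i.d. outliers, variables coupled to each other, and failure
mechanisms that need not follow a smooth eigenvalue ramp. Passing tests on
synthetic cohorts therefore demonstrate correctness of the *pipeline* and
calibration/power of the *statistics under the model*, not clinical
validity on real patients.

## Preprocessing

`preprocess_series()` applies, in order:

1. **Gap handling** (`handle_gaps()`): missing runs of ≤ 10 steps are
   filled with the mean of the two flanking observations; longer runs are
   spliced out and the flanks concatenated (the record shortens; splice
   positions are kept as provenance, and downstream windows treat the
   series as contiguous). Leading/trailing runs are deleted.
2. **Gaussian detrending** (`detrend_gaussian()`): the long-term baseline
   is estimated by Gaussian-kernel smoothing and subtracted. The kernel
   bandwidth is the one free parameter the original description leaves
   open; the default is `kernel_sd = 600` s (10 min), well below the 60-min
   analysis window, so only variation that is slow relative to the
   indicator windows is removed. The smoother uses a kernel truncated at
   ±4 SD with reflective boundaries, computed by FFT convolution. A single
   detrending pass is applied (a second pass would remove almost nothing,
   as the test suite checks).
3. **Outlier replacement** (`clip_outliers()`): residuals outside
   $\mu \pm 3\sigma$ are replaced by $\mu$, with $\mu,\sigma$ computed once
   per record on the input residual (no re-estimation, no per-window
   moments).

Records whose extubated interval is under 120 min are excluded
(`eligibility_filter()`); the boundary is inclusive — exactly 120 min is
retained — because the rule removes intervals *less than* twice the window.

## Indicators and trend tests

`compute_ews_trace()` slides a left-aligned window (default 60 min = 720
samples; 30 and 15 min for sensitivity analyses) forward by 1 min and
records the unbiased sample variance and the lag-1 autocorrelation
$r_1 = \sum_{i}(x_i-\bar x)(x_{i+1}-\bar x) / \sum_i (x_i-\bar x)^2$ per
window. Traces are timestamped by window start; constant windows yield an
undefined $r_1$ and are skipped. The implementation uses cumulative sums
(after centring on the global mean) and is verified against brute-force
per-window recomputation.

Each trace is tested for an increasing monotone trend with the
Mann–Kendall test using the Hamed–Rao variance correction (`mk_test()`):
the variance of the Kendall statistic S is inflated by
$1 + \frac{2}{n(n-1)(n-2)}\sum_i (n-i)(n-i-1)(n-i-2)\rho_s(i)$ over lags
whose rank autocorrelation exceeds the 95% normal band, floored at 1 so
the correction never *deflates* the variance; below 10 trace points the
test falls back to the uncorrected variance with a warning. P-values are
**one-sided for an increase** — the CSD hypothesis is directional, and
cohort proportions count *increases* — with a two-sided option exposed.
Within each record, the up-to-six (variable × indicator) p-values are
Holm–Bonferroni corrected (`holm_bonferroni()`, family = the record's own
tests), and a combination is flagged only when it passes Holm *and* its
Kendall $\tau$ is positive. `csd_ews()` packages the whole per-record
procedure as a single fit with `print`/`summary`/`coef`/`plot` methods.

## Cohort-level inference

`csd_cohort_analysis()` assembles per-record outcomes into the full report:

- **Proportions** of significant increases per cohort × ward × variable ×
  indicator, compared between the failure and control cohorts with a
  pooled two-proportion z-test, one-sided for "failure cohort greater"
  (that sidedness, applied to the printed whole-cohort heart-rate
  autocorrelation counts, is the only choice that reproduces their
  significance flag).
- **$\tau$ distributions** summarized as mean (SE) per cell with Welch
  t-tests; the tabulated p-values are two-sided (matching the printed
  worked example), while the directional one-sided variant is available
  for hypothesis tests such as the combined-strength comparison.
- **Classification metrics** per indicator (PPV, NPV, sensitivity,
  specificity, balanced accuracy), with the ROC/AUC computed under the
  **positive-$\tau$ convention**: records with $\tau \le 0$ are mapped to a
  sentinel below every threshold and can never be predicted positive; the
  curve is completed to (1, 1) and integrated by trapezoid. With no
  positive $\tau$ at all this degenerates to the chance diagonal,
  AUC = 0.5.
- **Combined strength**: per record, $\sum \max(\tau, 0)$ over its
  available coefficients (both indicators by default, autocorrelation-only
  via a switch), compared one-sidedly between cohorts and scored by AUC.
- **Weighted logistic models 1–6** (`fit_logistic()`): outcome ~ per-
  variable $\tau$ pairs, all six $\tau$s, the three vital-sign means, and
  all nine predictors, with case weights 10:1 (failure:success), AIC,
  Nagelkerke $R^2 = [1-(L_0/L_1)^{2/n}]/[1-L_0^{2/n}]$ on the weighted
  likelihoods with `n` the unweighted complete-case row count, and
  deviance ANOVAs between nested models on identical rows.
- **Age stratification** (`stratify_match()`, off by default since the
  generator draws ages identically across cohorts): controls are
  subsampled within quantile bins of the cases' age distribution; bins are
  a documented choice, as the original scheme is not specified.

`run_pipeline()` executes any combination of window lengths and cohort
pairs from a single seeded configuration, writes CSV report tables plus a
JSON manifest, and reconciles record counts across stages so no record is
lost silently.

## Numerical choices and degenerate inputs

- Exact OU discretization (no Euler bias); initial state from the
  stationary law; a time-varying $\lambda$ uses per-step coefficients.
- `lam_end` must stay strictly positive (the stationary variance diverges
  at 0); ramps are linear in time, the simplest schedule consistent with a
  steady approach to the bifurcation.
- Windowed statistics: global-mean centring before cumulative sums;
  within-window sums of squares floored at 0; constant windows skipped.
- Kendall $\tau$ is reported as tau-a ($S$ over all pairs); the tie term
  is subtracted from the uncorrected Var(S).
- Degenerate conventions: constant trace → $\tau = 0$, p = 1; pooled
  proportion 0 or 1 → z-test p = 1; zero-denominator metrics → `NA`
  markers; separation in a logistic fit is reported via `converged`.
- All randomness flows from explicit seeds; seeded helpers restore the
  caller's RNG state.

## Problem sizes used by the test suite

The packaged tests validate the statistics at sizes chosen to make
Monte-Carlo error small relative to the tested effect: OU moment checks on
40,000–50,000-sample paths over a $(\lambda, \sigma)$ grid; oracle
equivalence on 100+ random instances per operation; null calibration of
the uncorrected test on 2,000 white-noise traces; the family-wise error
study on 1,000 stationary synthetic records; and power/recovery studies on
40-record cohorts per ramp-severity level plus 2,000-row logistic designs.

## Known limitations

- **The corrected trend test is still anti-conservative on heavily
  overlapping windows.** With 60-min windows slid by 1 min, the indicator
  trace's serial correlation is extreme (lag-1 ≈ 0.97), the sample rank
  autocorrelation underestimates it on typical trace lengths, and the
  Hamed–Rao inflation is therefore insufficient: the test suite measures a
  per-record family-wise false-positive rate on stationary records that
  exceeds the nominal 5% (the corresponding acceptance check is expected
  to fail and is retained as a negative result). This matches the high
  control-cohort "significant increase" proportions the original analysis
  reports, and is a property of the method under these window settings,
  not of the implementation — which is verified against an independent
  re-implementation of the reference Hamed–Rao semantics. Block-bootstrap
  or surrogate-based nulls would be the natural refinement and are out of
  scope here.
- The synthetic cohort is a statistical, not physiological, model (see
  above); effect sizes measured on it say nothing about clinical effect
  sizes.
- Detrending attenuates but does not remove baseline components whose
  period is comparable to the kernel bandwidth; the defaults separate the
  scales by a factor of six.
- Windows spanning a splice point are retained (flagged via provenance)
  rather than excluded; with the default gap rates this affects a small
  minority of windows.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- cohort_config(n_cohort = c(8L, 30L, 0L, 0L),
                     duration_meanlog = log(2.4 * 3600),
                     duration_sdlog = 0.2, duration_max = 3.5 * 3600)
data <- generate_cohort(cfg, seed = 41)
run <- csd_cohort_analysis(data)
print(run)
run$performance
```
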